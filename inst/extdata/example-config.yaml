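# Example invadosim configuration: two-pool turnover model with ECM,
# regular pulsatile insertion at the control regimen.
params:
  T2_0: 200
  ECM_0: 1000
network:
  pools: XD
  include_ecm: yes
  include_shedding: no
  preassembled: yes
pools:
  X: {M_F0: 3, tau: 259}
  D: {M_F0: 7, tau: 26.0}
schedule:
  mode: pulsatile
  interval_mode: regular
  amount_mode: regular
  PH: {X: 0.3, D: 0.7}
  freq_fold: 1
  conc_fold: 1
  seed: 1
spatial:
  extent_um: [5, 5, 3]
  divisions: [51, 51, 1]
  n_invadopodia: 1
  mask_radius: 4
  D_timp2: 2.0e-11
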