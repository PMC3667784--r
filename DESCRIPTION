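Package: invadosim
Title: Kinetic Simulation of MT1-MMP Activity and ECM Degradation at Invadopodia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic modelling of the membrane protease MT1-MMP,
    its endogenous inhibitor TIMP-2 and the soluble gelatinase (pro)MMP-2 at
    invadopodia. Enumerates the full complex network (dimerization through
    the hemopexin domain, ternary and quaternary complexes, proMMP-2
    activation), integrates the resulting ODE system with a fixed-step
    fourth-order Runge-Kutta scheme, and layers on continuous or pulsatile
    vesicular turnover of MT1-MMP through two membrane pools, ECM
    degradation kinetics, and a compartmental 3D reaction-diffusion model of
    focal matrix degradation. Includes experiment presets for TIMP-2
    titrations, path-deletion analyses, transient-elimination insertion,
    stochastic insertion-schedule ensembles and frequency/concentration
    trade-off sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SystemsBiology, MathematicalBiology, CellBiology
Collate: 
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'parameters.R'
    'network.R'
    'kinetics.R'
    'turnover.R'
    'ecm.R'
    'experiments.R'
    'invadosim-package.R'
    'spatial.R'
    'io.R'
    'presets.R'
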