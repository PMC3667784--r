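---
title: "invadosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{invadosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
reaction network, the turnover and ECM layers, the spatial extension, the
numerical machinery, and the judgement calls made where the underlying
biology or published precedent left the design open.

## The complex-formation network

Three molecular players generate the network: membrane-anchored MT1-MMP
(`M14`), the soluble inhibitor TIMP-2 (`T2`) and soluble proMMP-2 (`M2`,
activated form `M2act`).  A membrane MT1-MMP unit ("arm") is in one of
three states — free, TIMP-2-bound, or carrying the TIMP-2·proMMP-2 pair —
and two arms dimerize through the hemopexin domain, giving nine membrane
species (three monomer states and six dimer states) plus the solution
species `T2`, `M2`, `M2act`, `T2.M2` and `T2.M2act`.
`enumerateSpecies()` produces this closed list; `buildCoreNetwork()` wires
it with mass-action reactions:

- reversible TIMP-2 binding to any TIMP-free catalytic site;
- reversible proMMP-2 docking onto membrane-bound TIMP-2;
- reversible docking of the preassembled `T2.M2` complex onto free
  catalytic sites (switchable; both the sequential and preassembled routes
  are on by default, because both lead to the same ternary complexes and
  neither can be excluded on kinetic grounds — the spatial model switches
  the preassembled route off, see below);
- reversible dimerization between any two membrane arms of the same pool,
  regardless of their TIMP-2/proMMP-2 load;
- irreversible processing of proMMP-2 inside the quaternary complex
  `M14.M14.T2.M2` — the only dimer with a proMMP-2-loaded arm *and* a
  TIMP-free partner arm — releasing `M2act`;
- reversible inhibition of `M2act` by free TIMP-2.

**Statistical factors.** Symmetric complexes use a site-counting
("distinct pair") convention: a rate constant is multiplied by the number
of equivalent sites or ligands it can act on (binding to a dimer with two
free arms runs at `2·kon`; dissociation of one of two identical ligands at
`2·koff`), and dimerization of identical partners runs at `k·[A]²` with
both copies consumed.  Detailed balance across the dimer ladder is then
automatic.

**ECM-degradation-competent activity.** The observable `M14a` weights the
free monomer at 1, the dimer at 2 and the half-inhibited dimer forms
`M14.M14.T2` and `M14.M14.T2.M2` at 1 — i.e. it counts free catalytic
sites among complexes not fully blocked by TIMP-2.  This is the only
weighting consistent with the dimer possessing twice the activity of the
other active forms.

**Variants.** `applyPathDeletions()` removes any subset of the five
inactive complexes (`M14.T2.M2.M14.T2.M2`, `M14.T2.M2`,
`M14.T2.M14.T2.M2`, `M14.T2.M14.T2`, `M14.T2`) together with every
reaction touching them; the operation is idempotent and commutative and
never leaves dangling references.  `addEctodomainShedding()` adds
irreversible shedding of the free membrane monomer to a diffusible
fragment `M14f` that binds TIMP-2 — a TIMP-2 scavenger.  The generated
reaction list is exportable as a plain-text table
(`exportReactionTable()`), and `readReactionTable()` rebuilds a network
from such a table, so a hand-curated reaction list can replace the
generated one after review.

## Kinetic parameters

Measured rate constants for this exact system are not available to the
package as machine-readable values, so it ships defaults drawn from the
published MT1-MMP/TIMP-2/MMP-2 kinetics lineage at order-of-magnitude
fidelity, fixed once and exposed through
`defaultKineticParameters()` and the YAML config (units: nM, s):

| constant | value | meaning |
|---|---|---|
| `kon_t2`, `koff_t2` | 2.74e-3 /nM/s, 2e-4 /s | TIMP-2 ↔ free MT1 site (tight, fast) |
| `kon_m2`, `koff_m2` | 1.4e-4, 4.7e-3 | proMMP-2 ↔ TIMP-2 (weaker) |
| `kon_dim`, `koff_dim` | 2e-3, 1e-2 | hemopexin dimerization |
| `k_act` | 2e-3 /s | proMMP-2 processing in the quaternary complex |
| `kon_t2m2a`, `koff_t2m2a` | 5.9e-3, 1e-4 | TIMP-2 ↔ active MMP-2 |
| `kon_ecm`, `koff_ecm`, `kcat_ecm` | 1e-3, 0.1, 1 | ECM binding/cleavage, MT1 classes |
| `kon_ecm_m2a`, `koff_ecm_m2a`, `kcat_ecm_m2a` | 1e-3, 0.1, 1 | same, active MMP-2 |
| `k_shed` | 1e-4 /s | ectodomain shedding (variant) |
| `M14_0`, `T2_0`, `M2_0`, `ECM_0` | 100, 100, 100, 1000 | initial concentrations |

Two consequences of this parameterization are worth knowing before
comparing against published curves.  First, because TIMP-2 binding is
tight (Kd ≈ 0.07 nM), the closed-model titration of `M14a_steady` against
TIMP-2 is essentially stoichiometric: ~1 nM of plateau lost per nM of
TIMP-2 until the ~100 nM of MT1-MMP sites is exhausted, then a collapse of
two orders of magnitude across 80–120 nM.  The "abrupt decrease at the
knee" is therefore a statement about the *relative* (log-scale) slope,
and that is how the package's checks formalize it.  Second, the slow
activation trickle converts all proMMP-2 on a ~10⁴ s horizon, and the
released active MMP-2 (whose TIMP-2 complex is tighter still) scavenges
inhibitor; the post-transient plateau of the closed model therefore drifts
upward to a higher equilibrium between roughly 10⁴ and 3×10⁴ s.  All
plateau-based metrics (`M14a_steady`, `t_transient`) consequently use the
*post-transient plateau* — detected at a relative spread of 5e-3 over a
50 s trailing window on a 600 s fine-step run — which is the quantity a
titration figure plots, not the t→∞ equilibrium.

## Integration

`integrateRK4()` assembles the mass-action right-hand side from the
reaction table and integrates it with classic fixed-step fourth-order
Runge–Kutta in a compiled core.  The default `dt = 1e-3` s resolves the
stiff initial transient with a wide stability margin; experiment presets
use documented larger steps (0.005–0.1 s) where the fastest rate constants
permit, and `auditStepSize()` performs the halve-and-compare audit on
demand (the tests require agreement to 1e-6 after halving).  Output
sampling is decoupled from `dt` via `out_stride`.  Insertion pulses are
instantaneous state jumps applied between steps on an event-aligned grid:
the integrator lands exactly on each event time (a shortened final step
per segment), applies the pulse operator, and resumes.  Non-finite states
abort with the offending time and species; concentrations in the
`-1e-6..0` range are clamped to zero on output only, so closed-system
conservation (checked to 1e-8 over 10⁴ s) is not disturbed.

`detectSteadyState()` declares a steady state when the observable's
relative spread over a trailing window (default 500 s) falls below
`rel_tol` (default 1e-4) and reports value, time and convergence —
non-convergence is explicit, never a silent last value.

An independent adaptive-step reference (`deSolve::lsoda` driven by
hand-written derivative functions) appears in the test suite only, as the
oracle for small networks; the shipped integrator never delegates to it.

## Membrane turnover through pools X and D

Two kinetically distinct docking pools carry MT1-MMP at the invadopodium:
X (maximum docking concentration `M_F0` = 3 nM, turnover time constant
259 s) and D (7 nM, 26.0 s); insertion and internalization rate constants
both default to the reciprocal time constant.  Continuous insertion runs
at `k_ins · M_F` where `M_F = M_F0 −` (docked MT1-MMP monomer
equivalents) — a complex occupies sites equal to its MT1-MMP content — so
no insertion occurs into a full pool.  Internalization removes every
membrane species of the pool at `k_int`.

**Cargo bookkeeping (open design point).** The enzyme itself is removed
without recycling — insertion always delivers fresh, TIMP-free MT1-MMP.
Its cargo, however, is released back: bound ECM returns to the matrix
(the cell removes its enzyme, not the substrate), and TIMP-2/proMMP-2
return to solution (as the `T2.M2` pair where they were paired).  Without
cargo release, internalization would silently drain the closed solution
reservoir of TIMP-2 within minutes and the entire TIMP-2 dependence of
degradation kinetics would be an artifact of inhibitor disappearance; a
clamped open bath would instead make pulse-scale inhibitor depletion
impossible by construction.  The closed-reservoir-with-recycling model
keeps solution totals exactly conserved (asserted in the tests).  Free
TIMP-2, proMMP-2 and `T2.M2` start at binding equilibrium for the
requested totals; an optional `clamp` argument provides the open-bath
variant.

**Pulsatile insertion.** The interval that makes pulsatile delivery match
the continuous model's maximal flux is `t_int0 = PH / (k_ins · M_F0)`;
with single insertions of 10% of `M_F0` this gives 25.9 s (X) and 2.6 s
(D).  `generateSchedule()` realizes regular trains (pulses at 0, t_int0,
2·t_int0, …), random intervals (exponential waiting times with the regular
mean — the maximum-entropy choice for "random intervals with the same
average"), and random amounts (uniform on [0, 2·PH], mean-preserving and
non-negative); schedules are reproducible from their seed.  Pulses clamp
to the free docking sites.  Frequency/concentration trade-off sweeps
rescale interval and amount reciprocally (folds 100/0.01 … 0.01/100 around
the control regimen).  Note a structural consequence of the docking
capacity: at concentration folds ≥ 10 a single pulse reaches or exceeds
`M_F0`, so part of each pulse is clipped and realized delivery falls below
the nominal time average — in this parameterization large-bolus regimens
therefore degrade ECM *more slowly*, not faster, and the package reports
that honestly rather than forcing the opposite trend.

**Transient elimination.** To suppress the insertion transient, newly
delivered MT1-MMP is apportioned across the pool's membrane complexes in
steady-state proportions (fractions weighted by MT1-MMP monomer content),
with the TIMP-2/proMMP-2 contained in inserted complexes drawn from the
solution species so totals stay physical.  The fractions are iterated to
the *fixed point of the eliminated dynamics*
(`poolSteadyFractions(eliminate = TRUE)`, relative tolerance 0.005): the
composition of the normal model is not a fixed point of
distributed-insertion dynamics, and distributing by non-self-consistent
fractions produces a spurious relaxation instead of the intended flat
trace.  At the fixed point the M14a trace is flat to well under 2% per
pool and overall, as required of the method.

## ECM degradation

Degradation uses explicit enzyme–substrate complexes, not lumped
Michaelis–Menten, because the analyses reason about the `M14a.ECM`
complexes directly: each of the four active MT1-MMP forms (per pool) and
active MMP-2 binds ECM reversibly and cleaves it at `kcat` (one ECM unit
consumed per event).  ECM-engaged MT1 complexes are pool-resident and
internalizable, do not bind further TIMP-2 while engaged (the simplest
reading of the state diagram; inhibition resumes on release), and the
"one enzyme, two substrates" rivalry between proMMP-2 processing and ECM
cleavage emerges from the shared free-enzyme pools without any extra
coupling term.  Metrics: `tauHalf()` (first crossing of ECM₀/2, linearly
interpolated; explicit NA when not reached), `initialDegradationRate()`
(least-squares slope over an initial window) and
`integratedActiveEcmComplex()` (cumulative trapezoid of the summed
`M14a.ECM` complexes, the direct correlate of degraded matrix).  Output
strides for τ_H runs are chosen so interpolation error is far below 0.1 s.

## The spatial model

`buildGrid()` divides a 5 × 5 × 3 µm extracellular volume into 51 × 51 × 1
compartments (xy cell ≈ 0.098 µm) and marks a central disc of 49
compartments (radius 4 cells, diameter ≈ 0.88 µm) as the invadopodium;
a five-invadopodium variant places four additional disjoint discs on the
diagonals.  ECM fills every compartment.  Membrane machinery — pools,
insertion/internalization, complex formation, proMMP-2 activation,
MT1-driven ECM cleavage — is embedded only in mask compartments; MMP-2
ECM degradation and TIMP-2 inhibition of MMP-2 run everywhere.  TIMP-2,
proMMP-2, active MMP-2 and the TIMP-2·MMP-2 complex diffuse (default
D = 2e-11 m²/s each); the preassembled `T2.M2` docking route is switched
off in spatial runs so the diffusing species are exactly these four.
Membrane reactions are interpreted as concentrations within
mask-compartment volumes — no separate surface-density unit system.

The stepper is operator-split: RK4 chemistry per compartment, then
explicit five-point finite-difference diffusion with zero-flux (closed
cuboid) boundaries, automatically sub-stepped to satisfy the FTCS
stability bound `dt < h²/(4·D_max)` with a 10% margin.  The single z
layer makes diffusion effectively two-dimensional, so the point-source
variance grows as `4·D·t` (verified against that closed form in the
tests) and diffusing mass is conserved to rounding.  Boundaries are
closed rather than an open bath; an open-bath boundary would be a
straightforward extension but is not what a matrix-filled chamber
approximates on these timescales.

## What the generator emulates, and what it does not

All inputs are synthetic by construction — the model's "data" are its
parameter set and the experiment descriptors.  The defaults emulate the
study conditions: 100 nM surface expression against 100 nM TIMP-2 and
proMMP-2 in the closed model; the printed pool capacities, turnover time
constants and 10%-of-capacity pulses in the turnover models; 0–500 nM
TIMP-2 titrations; and the 51×51 geometry with the TIMP-2 diffusion range
2e-11…2e-19 m²/s.  They do not emulate: measured rate constants (the
printed tables are not machine-readable; defaults are lineage-plausible,
so quantitative outputs such as τ_H values are order-of-magnitude, while
orderings, knees and structural effects are the reliable content);
mechanistic vesicle trafficking (insertion is a boundary condition);
stochastic chemistry (only insertion times/amounts are random; chemistry
is deterministic ODE); or the layered fibronectin/gelatin geometry of the
wet-lab assay.  Passing tests therefore certify the model's internal
structure and its qualitative biology, not quantitative agreement with
any particular cell line.

## Problem sizes and numerical choices in the test suite

The suite runs the closed model at `dt` = 5e-3 s over 600 s for plateau
metrics and 0.05–0.1 s for long horizons (10⁴–5×10⁴ s); ensembles use 30
seeds per condition at `dt` = 0.1 s over 12,000 s; the fold sweep uses 7
of the 13 fold-pairs at 8,000 s horizons; spatial checks run 20–60 s of
simulated time at D = 2e-12 m²/s for degradation comparisons and 30 s
across the full diffusion-coefficient range for transient persistence.
These sizes were chosen so every check completes comfortably on a laptop
while leaving each assertion's outcome unambiguous.  Ties in
steady-state detection resolve to the earliest window; τ_H crossings
resolve to the first crossing; the transient half-width of a series that
starts at its maximum is measured from the first sample.

## Known limitations

- Rate constants are lineage defaults, not fitted values; absolute τ_H
  and plateau numbers shift accordingly (every constant is configurable).
- The closed model's plateau is quasi-steady: complete proMMP-2
  conversion raises it on a ~10⁴ s horizon (see above).
- Large-bolus insertion regimens are capacity-limited by design; the
  package does not reproduce an efficiency gain for boluses at or above
  the docking capacity.
- No stochastic chemistry, no mechanical or deformable ECM, no moving
  invadopodium, no SBML export (the plain-text reaction table is the
  exchange format).
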