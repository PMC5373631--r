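---
title: "Methods: actin stability in podocyte foot processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actin stability in podocyte foot processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, how the parameter set was calibrated, how the synthetic
geometry is constructed and discretized, the numerical choices, and what
the results do and do not show.

## The kinetic model

Actin in a foot process (FP) is reduced to three pools: monomer `Ga`,
filament `Fa`, and crosslinked bundle `Bu`, all non-dimensional; time is in
arbitrary units. Filaments are produced by a filament-templated positive
feedback `alpha_f * Ga * Fa^h / (Fa^h + k^h)` — a lumped description of
Arp2/3-dependent branched nucleation downstream of nephrin and Rac1
signalling, saturating in `Fa` and engaging only once `Fa` is of order `k`
— and by a basal term `gamma_f * Ga * (Fa + 2*Ga)` that lumps elongation
(`gamma_f*Ga*Fa`) and spontaneous nucleation (`2*gamma_f*Ga*Ga`; the
factor 2 preserves mass when a dimer forms). Filaments are consumed by
bundling `alpha_b * Fa * (2*Fa + Bu)` (new bundles from merging filament
pairs, growth of existing bundles) and turnover `beta_f * Fa`. Bundles
additionally grow by direct monomer addition `gamma_b * Ga * Bu` and decay
with `beta_b * Bu`, which absorbs both depolymerization and
mechanical-stress-driven rupture. The three reaction rates sum to zero
locally, and a closed cell conserves total actin: in the non-spatial model
`Ga = total_actin - phi_fp * (Fa + Bu)` with `phi_fp = 0.20`, the measured
FP share of cell volume.

Key assumptions: no explicit molecular machinery (no nucleotide states,
filament-length distributions, or individual crosslinkers); `Fa` and `Bu`
exist only in FPs, while `Ga` exchanges freely with the cell body and
major processes, which act as a monomer reservoir; effacement is
represented purely as bundle loss (`Bu` below a threshold), with no
mechanics of membrane retraction.

## Calibration of the parameter set

Only a few rate constants are fixed a priori: `k = 0.22`, the baseline and
perturbed feedback strengths `alpha_f in {0.32, 0.1}`, the baseline and
raised bundling rates `alpha_b in {0.03, 0.05}`, the Hill exponent
`h = 2`, and `phi_fp = 0.20`. The remaining rates were calibrated, before
any package tests were written, to reproduce simultaneously:

1. a unique stable equilibrium with strong bundles at the baseline
   (`alpha_f = 0.32, alpha_b = 0.03`);
2. the measured 1:2 ratio of monomeric to polymerized actin at that
   equilibrium (imposed exactly by solving for `total_actin`);
3. three equilibria — two stable, one unstable, the weaker stable state in
   the effacement region — at `alpha_f = 0.1`;
4. loss of all stable equilibria with a sustained limit cycle at
   `alpha_b = 0.05`;
5. terminal collapse when both changes combine;
6. collapse of the oscillatory regime when the actin pool is scaled to
   70%, and stronger (yet still cyclic) bundles at 115%;
7. destabilization of the baseline when bundle turnover `beta_b` is
   halved (the injury used in the compensation scenarios);
8. local stability of the healthy state with `Ga` held fixed, so that the
   uniform field is a stable steady state of the spatial model.

The frozen set is `gamma_f = 0.002`, `beta_f = 0.06`, `gamma_b = 0.0035`,
`beta_b = 0.010`, `total_actin = 0.4666`, giving the healthy equilibrium
`(Fa, Bu, Ga) = (0.233, 1.322, 0.156)` and an oscillation period of about
340 time units in the raised-bundling regime. These values are the
package's study conditions and are shipped in
`inst/extdata/kinetic_params.json`; they are not re-tuned anywhere else.

The effacement threshold is 10% of the healthy-equilibrium bundle
concentration (0.132): it cleanly separates the collapsed branch from the
healthy branch in every calibrated regime, and is configurable everywhere
it is used.

**A known sensitivity.** The generalized model exposes the Hill exponent
and a separate nucleation coefficient (`hill_h`, `nucleation_n`).
Splitting nucleation from elongation at the same coefficient is an exact
identity (asserted in the tests). However, the *regime boundaries* of this
single frozen calibration are sensitive to structural changes: raising
`hill_h` from 2 to 4, or changing the nucleation coefficient by more than
roughly 10%, moves the baseline and weak-feedback sets across regime
boundaries unless the other rates are re-calibrated for the new structure.
Extensive constrained searches found no single parameter set that
satisfies all eight calibration constraints for both `h = 2` and `h = 4`;
the qualitative taxonomy itself (all four regimes, tristability,
asynchronous spatial collapse) is reproducible at either exponent with a
structure-specific calibration, but the package ships only the `h = 2`
set. Conclusions that depend on the location of a regime boundary should
be checked against this sensitivity.

## The idealized geometry

The generator (`build_idealized_podocyte()`) is the synthetic stand-in for
a microscopy reconstruction: it emulates an idealized quarter cell (two
reflective symmetry planes, symmetry factor 4) hitting measured aggregate
targets, not any individual cell's anatomy.

* **Cell body**: a quarter-sphere whose radius follows from the CB volume
  share (default 0.48 of the 420 um^3 body volume, matching the measured
  38% CB share of whole-cell volume), with the spherical surface exposed
  and the symmetry planes reflective.
* **Major processes**: 9 branch paths per quarter (36 whole-cell): 3
  primaries ending at branch points placed at 18 +/- 6 um from the
  centroid (mean exactly 18), each carrying 2 secondaries. Three far
  endpoints average exactly 39 um; the remaining tips extend 11 um (the
  measured mean branch length) past their branch point. Cross-sections are
  half-ellipses lying on the sagittal symmetry plane; the two semi-axes
  are solved so the CB+MP area and volume targets hold exactly given the
  total centerline length. The solution is a flattened ribbon (about
  3.9 x 0.5 um), consistent with real major-process morphology. Circular
  (or tapered circular) cross-sections cannot satisfy both targets at the
  required lengths, because a circle pins perimeter/area at 2/r.
* **Foot processes**: 233 cylinders of radius `2 / (A/V target)` =
  2/9 um and length 3.04 um, evenly spaced along the MP centerlines; the
  exposed area is the lateral surface (the attachment disc and the
  basement-membrane contact at the tip are excluded). This closed form
  reproduces the per-FP A/V of 9 um^-1 identically and the measured per-FP
  volume (0.47 um^3) to a fraction of a percent, so the assembled quarter
  cell lands within 0.1% of the measured totals (530 um^3, 1683 um^2)
  with no fitting.
* **Jitter**: optional seeded uniform jitter on branch-point and endpoint
  distances, re-centred after sampling so the two distance targets still
  hold exactly; used for robustness experiments, off by default.

What the generator does *not* emulate: real branching irregularity
(variable branch counts and angles, secondary-process nesting), non-uniform
FP spacing and sizes, the nucleus, and any membrane mechanics. Passing
tests on this geometry therefore demonstrate the *mechanism* — diffusion
time scales, volumes and surface-to-volume ratios are matched — not
agreement with any particular reconstructed cell. Whether real FPs are
uniformly distributed along processes is unknown; uniform spacing is the
neutral choice.

## Discretization

The spatial model runs on a one-dimensional-network finite-volume
discretization of the geometry rather than a full 3-D mesh. This is the
single largest simplification in the package: it preserves the diffusion
length scales, volumes, interface areas, and the FP-as-point-sink topology
that drive the resource-competition mechanism, but it cannot represent
azimuthal gradients within a cross-section or the detailed neck geometry
of a foot process.

Details that matter for accuracy:

* MP centerlines are split into cells of at most `axial_resolution`
  (default 2 um; FP-internal gradients are negligible at a 3 um FP
  length, so each FP is a single well-mixed cell).
* Cells abutting a junction are graded geometrically (0.25 um at the
  junction, doubling up to the nominal resolution) so junction
  conductances are resolution-independent.
* The cell body becomes concentric quarter-sphere shells whose interface
  conductances use the exact radial form (effective area `pi*a*b` between
  shell centers `a < b`), second-order accurate under refinement.

With these choices the steady stratification profile changes by 1.5%
between 2 um and 1 um resolution and by 0.7% on the next refinement
(well inside the 2% design target), and total volume is conserved exactly.

## Stratification (cell-body identification)

The CB filter solves the steady linear balance of a species synthesized
uniformly per volume, diffusing between compartments, and exported across
the membrane proportionally to local concentration — the classic
uniform-heat-generation/convective-boundary analogue. Only the ratio of
export to diffusion matters for the relative profile; the defaults
(`D = 10` um^2/time, `export_coeff = 0.15` um/time, `synthesis_rate = 1`)
were chosen so the 0.9-of-maximum threshold reproduces the qualitative
split: every CB cell stays at or above 0.93 of the maximum while all
process cells fall below 0.88. Increasing export steepens the profile
monotonically (asserted as a property test over a 10x range).

## Two-compartment extension

Two FP fractions share one instantly mixed monomer pool; compartment 2
receives a feedback increment. The transient stimulus is a linear rise
over `t_rise = 60` from onset `t0 = 40`, then exponential decay with
`tau = 10`; amplitude is expressed relative to baseline (`amplitude = 1`
means the stimulated feedback transiently doubles). The shape parameters
were calibrated once so the three transient outcomes occur at relative
amplitudes 0.5 (both recover), 1 (the *unstimulated* fraction collapses,
drained of monomer), and 2 (the stimulated fraction overshoots and crashes
after withdrawal, and the other fraction inherits the released monomer).
The bisected switching amplitudes on the default settings are about 0.55
and 1.8; outcome identity, not the pulse's analytic form, is the claim,
and the scan utilities expose the sensitivity to shape.

Steady states are declared when the maximum time-derivative stays below
1e-8 at 10 consecutive checkpoints; oscillatory (non-convergent) grid
points in the sustained-response surface are flagged, never silently
reported as steady.

## Spatial scenarios and diagnostics

The monomer diffusion coefficient `D_Ga = 3` um^2/time was chosen (it is
not derivable from the non-dimensional kinetics) so that the global
bundling-step scenario desynchronizes on the observed time ordering:
perturbation at t = 40, visible heterogeneity by t ~ 1200, extensive
collapse by t ~ 2400. At 1000-fold larger `D_Ga` the spatial model
collapses onto the non-spatial ODE (and, with a two-region stimulus, onto
the two-compartment model) to within 1% — the well-mixed limit tests.

Effacement is detected per FP as bundle concentration staying below
threshold from some time t* through t* + `persistence_window` (default
10% of the record) and through the end of the record; records shorter
than the window yield an explicit unresolved status. In the compensation
scenarios the default horizon is `t1 + 1000` so early and late
interventions are observed for the same post-intervention duration —
otherwise the later run is censored and survivor counts are not
comparable.

The asynchrony index is `(1 - mean pairwise correlation)/2` of the per-FP
bundle timecourses over a window (0 = synchronous, 1 = anti-phase;
constant records are excluded and an all-constant record scores 0).
Pattern divergence is the fraction of FPs whose survived/effaced status
differs between two runs on the same network.

Compensation scenario values (the injury and rescue magnitudes are design
choices, selected so the compensated kinetics are stable or cycle above
the effacement threshold): injury halves `beta_b` at t = 0; rescues at
`t1` either restore `beta_b`, halve `alpha_b` (to 0.015), or double
`alpha_f` (to 0.64; this one leaves a sustained oscillation whose bundle
minimum stays above threshold).

## Numerical choices

* Integration: `deSolve::lsoda` for the reduced ODE systems (relative
  tolerance 1e-8), `lsodes` (sparse) for the ~800-state network model
  (1e-7); states are clamped non-negative inside the right-hand side;
  conservation drift on full scenarios stays below 1e-12 relative.
* Equilibria: dense sign-change grid scan (uniform grid augmented with a
  log-spaced sub-grid near the origin, where collapsed-branch roots scale
  like `gamma_f*total^2/beta_f` and can underflow a uniform grid),
  followed by a damped Newton polish with numeric Jacobians; residual
  acceptance at 1e-10; roots outside the conservation simplex are
  discarded; output sorted by `Fa`. The tests compare root counts against
  an independent recursive sign-scan bisection oracle on 20 random
  parameter sets.
* Nullclines: per-`Fa` column scans plus a transposed per-`Bu` scan that
  resolves near-vertical curve sections; branch indices refer to the
  column scan.
* Oscillation detection: at least 3 interior peaks with prominence above
  1% of the observed amplitude in the late half of the record; the
  classification horizon (default 6000) is about 50 times the slowest
  linearized timescale of the calibrated sets.
* Regime classification order: bistable if two stable states straddle the
  effacement threshold; monostable-healthy if the only stable state is
  outside the effacement region; otherwise integration from a 3x3 grid of
  initial conditions distinguishes sustained cycles from terminal
  collapse, with an explicit UNRESOLVED fallback.

## Problem sizes

The shipped defaults keep every analysis at desk scale: the quarter-cell
network has ~350 cells (233 FPs), scenario horizons are 1500-2500 time
units, the acceptance script runs in seconds, and the full test suite
(including all spatial scenarios, the oracle comparisons, and the
amplitude scans) in about half a minute on one core.

## Known limitations

* The chaotic sensitivity that is part of the scientific claim also caps
  reproducibility of *patterns*: between 2 um and 1 um resolution the
  global-bundling scenario's survivor count shifts by about 5% of the FP
  population (73 vs 84 of 233) and the identity of the effaced set changes
  substantially. Counts and ensemble statistics are meaningful; per-FP
  fates are not transferable across discretizations or perturbation
  magnitudes — asserting pattern identity would be wrong, and the tests
  deliberately do not.
* One kinetic calibration is shipped; regime boundaries move under
  structural changes to the feedback term (see the calibration section).
* The 1-D network discretization cannot capture sub-cross-section
  gradients; the localized-stimulus scenario reproduces mixed
  within-region and adjacent collapse, but boundary geometry effects seen
  in full 3-D simulations are only coarsely represented.
* No mechanics: effacement is a concentration threshold, and geometry
  never deforms over time.
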