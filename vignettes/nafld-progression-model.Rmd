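---
title: "A multi-scale model of FFA-driven liver disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale model of FFA-driven liver disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nafldsim)
```

## The model

Non-alcoholic fatty liver disease (NAFLD) progresses over decades, driven
by a persistently elevated supply of free fatty acids (FFAs) from insulin
resistant adipose tissue. `nafldsim` represents the liver as an ensemble of
`N` macroscopic *liver units* (LUs, centimetre scale), each a well-mixed
two-compartment system - a vascular (sinusoidal) compartment exchanging
FFAs with plasma, and a cellular compartment metabolizing them - plus one
shared plasma FFA pool that couples all units. Heterogeneity of perfusion,
metabolic capacity and repair capacity across units is the central object
of study: it decides whether an FFA challenge remains a local nuisance or
triggers cascading organ failure, because every failing unit shifts its
share of the FFA load onto the survivors.

### Unit metabolism (minutes)

Per unit, three pools are tracked (concentrations in mM; the TAG pool in
esterified FFA equivalents): sinusoidal FFA, cellular FFA, and TAG.

* uptake: `v_u = k_u (FFA_sin - FFA_cell)` - bidirectional, the unit can
  release FFAs when the cellular level exceeds the sinusoidal one;
* beta-oxidation: `v_beta = k_beta FFA_cell`;
* esterification: `v_+TAG = k_+TAG FFA_cell (FFA_cell / FFA_crit)^2` -
  cubic in cellular FFA. The super-linear factor models the upregulation of
  lipogenic enzymes with FFA load; it makes TAG synthesis the dominant sink
  at high FFA and buffers the cellular FFA concentration roughly as the
  cube root of the load;
* TAG hydrolysis `v_-TAG = k_-TAG TAG` and VLDL export
  `v_VLDL = k_VLDL TAG`;
* a constant de novo lipogenesis flux `v_denovo`.

All fluxes are expressed per total LU volume, so 1 mM/min corresponds to
100 umol/100 mL/min; this makes simulated fluxes directly comparable to
measured hepatic transport rates. The intact-cell fraction `eta` (below)
scales every cellular flux: a unit that has lost half of its functional
hepatocytes metabolizes at half speed.

Perfusion follows a Poiseuille law through the sinusoidal geometry
(radius 3.15 um, length 375 um, volume 1.169e-11 L). The default blood
viscosity is back-computed from this geometry so that a pressure gradient
of 0.2 drives exactly 1 mL of blood per mL of liver per minute, the
textbook hepatic perfusion rate. The flows in the sinusoidal balance are
normalized per vascular volume (about 10 min^-1 at a vascular volume
fraction of 0.1); the ratio `Omega_cell/Omega_s = 9` converts cellular
uptake into a sinusoidal concentration change.

The plasma pool receives FFAs from adipose tissue at rate `v_at`
(baseline 1.17 mM/min), loses them to extra-hepatic consumers with rate
constant `k_et = 2.34 min^-1`, and exchanges with every unit through the
arterio-venous concentration difference. The volume ratio scaling that
exchange is not observable at the unit level; it is collapsed into one
dimensionless *closure constant*, calibrated once so that the healthy
reference liver at the baseline release rate settles at a plasma FFA
concentration of 0.26 mM (`calibrate_liver_closure()`). The constant is
then reused unchanged for every scenario and every sampled liver.

### Damage and repair (months to years)

Each unit carries an intact-hepatocyte fraction `eta` in `[0, 1]`:

```
d eta / dt = k_r eta^2 (1 - eta) - k_d_eff(FFA_cell) eta
```

Regeneration needs interacting intact cells (`eta^2`) and is stimulated in
proportion to the damage (`1 - eta`); the product peaks at `eta = 2/3`.
Damage is first order in `eta` with a rate constant that is basal
(`k_d = 3.456e-4 d^-1`) below the cytotoxicity threshold
(`FFA_critical = 0.1` mM) and amplified linearly above it (factor
`1 + gamma (FFA/FFA_critical - 1)`, `gamma = 30`). The interplay of the
cubic regeneration curve and the linear damage law creates bistability:
for effective damage rates below `k_r/4` a stable high-`eta` state
coexists with the extinct state `eta = 0`; beyond `k_r/4` (at the default
constants, a cellular FFA of about 1.69 times the threshold) the unit
inevitably collapses. `stable_eta()` and `damage_bifurcation()` expose the
closed forms; transient insults (toxins, infections) enter as Gaussian
bumps added to the damage rate constant (`hit_event()`, default strength
six times basal, width one year).

### Two-timescale integration

Metabolic pools relax within minutes, `eta` moves over months, disease
runs over decades. `simulate_diurnal()` integrates the full minute-scale
system (stiff, `deSolve::lsoda`) with `eta` frozen - used for the diurnal
feeding-cycle experiments, in which the release rate oscillates
cosinusoidally three times per day between 0.35 and 2.45 mM/min.
`simulate_progression()` instead advances `eta` day by day: at each outer
step the plasma concentration and all unit states are set to their
quasi-steady values (a safeguarded Newton solve of the coupled balances),
then `eta` takes one Heun (two-stage) step with the equilibrium recomputed
at the predictor stage. The scheme is second order in the outer step;
halving the default 1-day step changes the 30-year outcome by less than
1e-3 (verified in the test suite). Units whose fraction falls below 1e-6
are treated as extinct - the absorbing state would otherwise be escaped
through floating-point dust amplified by the `eta^2` regeneration term.

## Virtual livers and what the generator emulates

`sample_virtual_liver()` draws per-unit parameters from Normal
distributions centred on the reference values with a relative standard
deviation `cv` (default 20%, matching the magnitude of regional blood-flow
and protein-abundance variation seen across real livers). Draws below 5%
of the mean are redrawn, a truncation that protects against non-physical
rates while perturbing the distribution negligibly at the default spread.
Two draw sets are used:

* progression experiments vary perfusion (one `dp` knob scaling both
  pressure gradients of a unit), `k_u`, `k_beta`, both TAG-removal
  constants, `k_+TAG`, and the damage/repair pair `k_d`, `k_r`;
* the diurnal parameter-noise experiment varies every per-unit constant of
  the kinetic table independently, including the two pressure gradients.

A *homogeneous* liver shares a single draw across all of its units - the
limiting case of coarse-grained heterogeneity. Cohorts derive each
liver's RNG stream deterministically from a master seed and the liver
index, so ensemble results are independent of evaluation order and
bit-reproducible.

The generator emulates static, spatially uncorrelated functional
heterogeneity. It does not emulate spatial correlation between
neighbouring units, adaptive upregulation of surviving tissue, zonation
within lobules, inflammation-driven parameter drift, or measurement noise
- so passing ensemble tests demonstrate the consequences of the modelled
heterogeneity, not agreement with any particular patient population.

## Observables

* `tfh()`: the total fraction of intact hepatocytes, mean of `eta`.
* `steatosis_fraction()`: share of units whose *tissue* TAG content
  exceeds 30 mM. During progression the scored quantity is
  `eta * TAG_qss`: only intact cells synthesize and store TAG, so failing
  units lose their steatosis as their cell mass disappears - this is what
  makes ensemble steatosis rise right after the challenge and decline as
  the disease advances. The threshold comparison is strict; a unit at
  exactly 30 mM counts as neither steatotic nor spared (a measure-zero
  convention).
* `steatosis_pattern_score()`: (fraction of spared units) x (mean TAG of
  steatotic units), a contrast measure of the regional fat pattern.
* `ensemble_summary()`: outcome classes per liver (complete failure below
  TFH 0.05, marginal disease above 0.95 - the named categories are not
  quantified in the source material, so these thresholds are package
  conventions), rank correlations of pattern scores with the final TFH,
  and the ensemble TAG coefficient of variation.

## Numerical and design choices

* **TAG-removal constants.** The reference table pairs 0.006/0.018 min^-1
  with hydrolysis/export; only the swapped assignment (hydrolysis 0.018,
  export 0.006) satisfies the printed steady-state fluxes
  (14 = 11 + 3.5 umol/100 mL/min), so the swap is the default and the
  literal pairing remains selectable (`swap_tag_constants = FALSE`).
* **`eta` on VLDL export.** By default the intact fraction scales every
  cellular flux, including VLDL export; `eta_on_vldl = FALSE` in
  `lu_metabolic_rhs()` selects the alternative reading.
* **Esterification threshold.** `FFA_crit` of the esterification law is
  set equal to the cytotoxicity threshold (0.1 mM); no independent value
  exists, and only this choice reproduces the reference esterification
  flux.
* **Perfusion heterogeneity** acts through the pressure gradients, not the
  radii: `dp` is the single progression knob; the noise experiment draws
  the two gradients independently.
* **Quasi-steady closure.** Solving the metabolic balances instead of
  integrating them exploits that the fast subsystem is strictly monotone:
  the cellular balance has a unique root (Newton from a warm start, ~2
  iterations in the inner loop), and the plasma balance is strictly
  decreasing in the plasma concentration. The whole cohort is advanced in
  lockstep as matrices, which keeps a 100-liver, 100-unit, 35-year run in
  the one-minute range.
* **Pre-challenge equilibration.** Progression runs start fully intact at
  the baseline release rate; the healthy fixed point is reached within
  months, long before the default challenge onset at year 5 (horizon: 30
  years after onset, 35 simulated years in total).
* **Problem sizes.** The shipped experiments use 100 units per liver and
  100 livers per cohort (10/100/1000 units for the granularity sweep, 30
  livers per level in the test suite), diurnal runs of 6-10 days at
  minute resolution, and 1-day outer steps for progression.

## Known limitations

* Under the default calibration, the standard challenge (release rate
  1.17 to 1.76 mM/min) places the *reference* unit's cellular FFA at about
  0.096 mM - just below the 0.1 mM cytotoxicity threshold. Combined with
  the cube-root buffering by the esterification sink, 20% parameter
  heterogeneity then produces only mild 30-year progression: most units
  stabilize at high intact fractions, complete unit failure requires
  extreme parameter combinations, and the tissue TAG of a unit rarely
  crosses the 30 mM steatosis threshold. Scenario observables that depend
  on widespread unit failure (broad outcome distributions, large steatosis
  excursions, pattern-score prognosis) are correspondingly weak at the
  default constants. The constants are nevertheless kept as published
  values rather than re-tuned; the scenario machinery itself is agnostic
  to them, and stronger damage parameterizations can be explored through
  the configuration interface.
* The diurnal plasma excursion follows the seven-fold swing of the release
  rate almost quasi-statically, because the extra-hepatic clearance
  (2.34 min^-1) is fast compared to the 8-hour forcing period; the
  simulated plasma band is therefore wider, and the TAG limit-cycle ratio
  larger, than the physiological ranges the forcing amplitudes were
  originally quoted with.
* No inter-unit flow redistribution after failure beyond the shared
  plasma pool; no portal-versus-arterial split; no explicit immune,
  stellate-cell or fibrosis variables - repair is the lumped `v_r` law.
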