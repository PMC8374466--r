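---
title: "Methods: the water-driven engine and the ideotyping procedure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the water-driven engine and the ideotyping procedure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ideocrop)
```

`ideocrop` simulates crop growth on a daily time step in the water-driven
tradition: the crop's productive engine is transpiration, everything else
(canopy, soil water, stress) exists to determine how much water the crop
transpires and what fraction of the resulting biomass is harvestable. This
vignette explains the model, the choices made where the underlying
formulations are conventionally left open, and exactly what the synthetic
experiments shipped with the package do and do not demonstrate.

## Model structure and assumptions

A season runs from sowing (day 0) to maturity at `d_maturity` calendar
days after sowing (DAS). Each day is processed in a fixed order chosen to
avoid same-day circular dependence:

1. phenology stage and root depth for the day,
2. the four stress coefficients from the *previous* end-of-day soil-water
   state,
3. canopy-cover dynamics,
4. evapotranspiration partitioning and the root-zone water balance,
5. biomass and harvest-index accrual from the transpiration actually
   extracted.

Phenology is driven by calendar days, the scale on which the shipped
ideotypes are defined; a degree-day helper (`gdd()`, capped daily mean
above a base temperature) is provided for thermal-time work but is not
used by the engine. Calendar boundaries belong to the later stage: day
`d_emergence` is the first vegetative day. Because flowering and
harvest-index buildup overlap, the reported stage switches to
`hi_buildup` on the first day buildup accrues and holds that label until
senescence, so the stage sequence is monotone.

### Canopy

Unstressed canopy cover follows the classic two-piece exponential in
`canopy_cover_unstressed()`: `cc0·exp(cgc·t)` below half the maximum
cover, then an exponential approach `ccx − 0.25·(ccx²/cc0)·exp(−cgc·t)`.
These are the defining equations of the canopy growth coefficient in this
model family; the package adopts them because the coefficients of the
shipped ideotypes are only meaningful under these forms. The *discrete*
daily step does not integrate an ODE: it inverts the closed form at the
current cover ("re-anchoring") and advances virtual time by
`ks_expansion` days. Two consequences:

- expansion stress `ks_expansion` scales the effective growth rate
  exactly (`ks·cgc`), and
- iterated unstressed steps reproduce the closed form to floating point,
  which the test suite checks at every day of the growth phase (tolerance
  1e-6).

Senescence decline uses the relative decay
`cc_on·(1 − 0.05·(exp((cdc/ccx)·t) − 1))` anchored at the cover when
decline began, floored at zero. Decline begins at `d_senescence`, or
earlier when `ks_senescence < 1` has persisted for `early_sen_run`
consecutive days (default 1); stress-triggered decline advances the decay
clock by `1 − ks_senescence` per day, and growth resumes if the stress
lifts before the calendar date. Cover that has collapsed below `cc0`
re-anchors at the start of the growth curve.

### Soil water

The root zone is a single homogeneous bucket of depth `zr` (linear
deepening from `zr_min` at emergence to `zr_max` at `d_max_root` — the
simplest monotone rule consistent with endpoint-only information). Newly
rooted soil enters at the profile's initialization content. Within a day:
infiltration up to pore space (the remainder is reported as
`non_infiltrated`; no curve-number runoff), drainage of a `tau` fraction
(default 0.75) of the excess above field capacity capped at `ksat`, then
soil evaporation, then transpiration capped by the extractable store
above wilting point. Soil evaporation is two-stage: energy-limited at
`ke_max·(1 − CC*)·ETo` until a readily-evaporable-water budget (default
9 mm) has been extracted since the surface was last wetted, then
square-root-of-time decay; evaporation cannot draw the store below half
the wilting-point content. The daily balance closes algebraically and the
engine accumulates `|residual|` over the season — a whole 140-day run
closes to ~1e-12 mm, far below the 1e-4 mm the test suite demands.

The default soil is a clay loam (PWP 0.23, FC 0.39, SAT 0.50 v/v, Ksat
125 mm/d), the model family's standard hydraulics for that texture; every
value is overridable via `soil_profile()` or a soil file. The initial
condition defaults to field capacity (configurable), a reasonable state
for a temperate site after spring recharge.

### Stress coefficients

Relative depletion `D = (FC − θ)/(FC − PWP)` drives three linear-ramp
coefficients (expansion, stomatal, senescence): 1 below `p_upper`, 0 at
`p_lower`, linear between. Defaults: expansion 0.20–0.60, stomatal
`p_upper` 0.50 (moderate) or 0.35 (strong) with `p_lower` 1, senescence
0.70–1. Aeration stress ramps from 1 at `SAT − margin` to 0 at
saturation, with margin 5 vol-% for a `sensitive` crop (3% moderate, 1%
tolerant). The categorical harvest-index responses map to adjustment caps
of 0/10/20% for none/moderate/strong. All of these numeric stand-ins for
categorical settings are documented fields of `stress_settings()` and can
be overridden; the category-to-number mapping is a package decision, made
once, because a simulator needs numbers where the source
parameterizations give categories.

### Production

Daily biomass is `WP*·Tr/ETo` (g m⁻²); the engine verifies the global
identity `B = WP*·Σ(Tr/ETo)` to 1e-9 relative. Normalizing by daily ETo
is the interpretation adopted here because it is what makes `WP*`
transferable across climates — the property that justifies moving a
parameter set between a baseline crop's home environment and a new one. A
raw `Σ Tr` mode is available (`simulation_control(normalized = FALSE)`)
for comparison. Transpiration demand is
`ks_stomatal·ks_aeration·kc_tr_max·CC*·ETo` with `kc_tr_max` 1.10 and
`CC* = 1.72·CC − CC² + 0.30·CC³`, the standard convexity adjustment.

The harvest index is zero before buildup onset (flowering onset plus a
configurable offset, defaulting to 0 — onset-at-flowering is assumed
where the alternative, onset at flowering's end, cannot be ruled out from
stage-duration tables alone). It rises linearly to `hi_ref` over
`d_hi_buildup` days and freezes. Stress adjusts it multiplicatively,
pro-rata over the relevant windows and capped by category: upward for
restrained vegetative growth and for expansion stress during buildup,
downward for stomatal closure during buildup; severe depletion beyond
`p_upper_flowering` during the flowering window imposes a pollination
penalty. The adjusted HI is additionally capped at 1 — the harvestable
fraction cannot exceed the whole biomass — which matters for the fibre
ideotype, whose `hi_ref` of 1.0 encodes "yield = total above-ground
biomass" (whether stem-only partitioning was intended for fibre is not
decidable from the source tables; total biomass is the literal reading
and is what the package implements).

### The ideotypes

`builtin_ideotype()` ships grain hemp, fibre hemp, and the sugarcane
baseline from which they were derived. Three entries need explanation:

- `cc0` is not tabulated anywhere; it is derived as plant density times a
  per-seedling cover of 5 cm² (140 000 plants/ha → 0.007), the standard
  convention in this model family. Both factors are fields.
- The flowering-stress threshold 0.90 is assigned to the *grain*
  ideotype and left absent for fibre: grain yield passes through
  pollination, fibre yield does not, so a flowering-failure threshold is
  only meaningful for the grain crop. It is an overridable field.
- The sugarcane baseline has no tabulated emergence day or flowering
  stage; the package uses 7 days (regrowth-type establishment) and an
  undefined flowering calendar, under which HI buildup falls back to
  starting at emergence. Its plant population is set to the family's
  default sugarcane density, 140 000 plants/ha.

## Synthetic weather

`generate_synthetic_weather()` emulates a temperate, rain-fed site of the
Po-valley type: a seasonal Tmax sinusoid (annual mean 18 °C,
half-amplitude 11 °C, peak near day-of-year 205, day-to-day noise SD
2.5 °C), a stochastic diurnal range (mean 9 °C, truncated at 2 °C so
Tmin < Tmax for every seed), intermittent rainfall (30% wet days,
exponential intensities with mean 6 mm) and a smooth seasonal ETo curve
(mean 2.8, half-amplitude 2.2 mm/d, floored at 0.1). These defaults were
chosen once as a realistic temperate climate able to drive a 140-day
summer season and are not tuned thereafter.

What the generator does *not* emulate: persistence (wet/dry spells are
independent Bernoulli days), temperature–rain correlation, heat waves,
radiation or wind (ETo is an input here, as it is in the model family's
climate files — no internal Penman–Monteith), and inter-annual variance
structure. Consequently, passing tests demonstrate the engine's internal
consistency and the calibration procedure's behaviour under plausible
forcing — they do not validate the ideotypes against real field seasons,
which would require the original station records.

Monthly or decadal aggregates can be downscaled with
`downscale_to_daily()`: temperature and ETo by a mean-preserving
piecewise-linear interpolation through period-midpoint nodes (the
node-to-mean map is solved exactly, so re-aggregation returns the inputs
to ~1e-9), rainfall by placing each period's total on seeded
pseudo-random wet days, preserving dry spells rather than smearing. The
downscaling rule the original software applies internally is not
published; this scheme is a documented stand-in and is recorded in the
output's `scheme` attribute.

## The sequential calibration

`calibrate_sequential()` formalizes the ideotyping procedure: parameter
groups are processed strictly in order — life cycle, canopy growth rate,
maximum canopy cover together with the harvest index (the canopy-cover
analogue of a leaf-area-index step, since the engine carries no LAI
state), then harvest-index buildup. The search itself is a deterministic
coordinate grid (15 points per parameter over its bounds, one refinement
pass at 1/7 of the coarse spacing on a lattice anchored at the lower
bound): the published procedure was literature-guided manual iteration,
so any automated search is a stand-in, and a grid was chosen over local
optimizers precisely because it is reproducible, order-deterministic and
trivially testable. A candidate is accepted only when it strictly lowers
the objective (ties resolve to the smaller value), which makes an
already-optimal base a fixed point and renders the accepted-objective
sequence nonincreasing by construction.

The objective averages, with equal weights, each observed variable's RMSE
normalized by its observed mean — the one-scale compromise for mixing
t/ha and day counts, configurable in principle by pre-scaling the
observations. Candidates that violate a parameter invariant or exceed the
supplied weather are infeasible (`Inf`); an observed quantity a candidate
cannot produce at all (an observed flowering day for a crop without a
flowering calendar) incurs a large finite per-element penalty instead, so
the search retains a gradient on the quantities it can produce. Within
the life-cycle step, senescence and maturity are searched first: until
the cycle end is in range, candidate values for the earlier landmarks are
either unsimulable or violate the stage ordering.

The shipped recovery experiments perturb one parameter of the grain
ideotype by ±25%, generate noise-free observations from the perturbed
"truth" on seeded synthetic weather, and recalibrate the relevant step
from the unperturbed base: `cgc` is recovered within 10% and
`wp_normalized` and `hi_ref` within 5% across the tested seeds (five per
parameter in the acceptance suite, three in the acceptance script). These
are scaled-down, known-truth analogues of a calibration campaign; they
establish identifiability under the model's own assumptions, not against
field data.

## Numerical choices and degenerate inputs

- Stage boundaries belong to the later stage; `mature` is absorbing.
- The canopy step guards the closed-form inversion: cover within 1e-12
  of `ccx` stops advancing, cover below `cc0` re-anchors at `t = 0`.
- Depletion, stress coefficients and HI are clamped to their domains
  after every update; `theta` cannot leave `[0, theta_sat]`.
- `rmse()` on a single pair is the absolute difference; empty and
  mismatched inputs are distinct errors.
- Grading boundaries: exactly 10% and 20% are `good`, exactly 30% is
  `fair`, following the inclusive reading of "10–20%" and "20–30%".
- A biomass increment with `tr > 0` but `eto = 0` is an error (undefined
  normalization), not a silent zero.
- Crop and soil files are flat key-value text with unit-suffixed keys;
  the writer emits full precision (17 significant digits) so
  writer∘reader is the identity.
- Observation noise in `make_truth_observations()` is Gaussian,
  truncated at zero for the nonnegative observed quantities.

## Problem sizes used by the shipped experiments

The test and acceptance experiments use 140-day seasons on 550-day
synthetic series, 20 seeds for the rainfall-monotonicity property, 5
seeds per parameter (3 in the acceptance script) for recovery, and 200
replicates for the observation-noise spread check. These sizes were
chosen as the smallest at which the stochastic checks are stable.

## Known limitations

- No photoperiod response: hemp is a short-day plant, and a calendar-day
  phenology fixed at one planting date cannot extrapolate flowering to
  other sowing windows or latitudes.
- No temperature, fertility, salinity or CO₂ modulation of growth; no
  cold-stress module. The thermal parameters bound `gdd()` only.
- Single-bucket soil: no layering, capillary rise or water table.
- The grain/fibre difference in `cgc` (0.24917 vs 0.11917) is inherited
  as published, without reconciliation.
- One crop per run: a dual grain-plus-fibre harvest from a single canopy
  is not represented; run each ideotype separately.
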