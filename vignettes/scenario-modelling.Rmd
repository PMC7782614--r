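---
title: "Scenario modelling of eelgrass occurrence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario modelling of eelgrass occurrence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

Eelgrass occurrence is modelled per 100 m grid cell as a Bernoulli
outcome whose probability depends on two physical predictors, each a
5-year mean:

* **PFD** — photosynthetic photon flux density 0.5 m above the sea
  floor (the canopy top), in μmol photons m⁻² s⁻¹;
* **MOV** — the maximum wave-generated orbital velocity at the bed, in
  m s⁻¹.

The occurrence model is a binomial generalized additive model on the
logit link with one smooth term per predictor,

$$\operatorname{logit} p = \beta_0 + s_1(\mathrm{PFD}) + s_2(\mathrm{MOV}),$$

fitted to a **prevalence-balanced** sample: the majority class of the
survey is subsampled so presences and absences are equally numerous.
Balanced prevalence is what licenses reading the fitted probability
directly as an expected plant-encounter rate, i.e. percent cover, and
therefore summing `probability × cell area` into an expected meadow
area. This coverage reading is the backbone of every downstream summary
(area series, depth profiles, attribution), so the package checks at fit
time that the mean fitted probability matches the training prevalence.

Key assumptions inherited by everything downstream:

* the distribution is in equilibrium with its environment — presence
  wherever conditions suit, absence elsewhere — so a model trained on a
  baseline survey may be evaluated under future predictor fields;
* cells are independent; there are no dispersal, colonization-lag or
  sediment-feedback dynamics;
* salinity is not a predictor (in the brackish study region it adds no
  discrimination over light and waves).

## Predictor derivation

**Light.** Surface irradiance (W m⁻²) converts to photon flux with the
factor 4.15 μmol photons J⁻¹. A single monthly climatology represents
the whole domain (a single-station simplification; the packaged default
is a 12-value synthetic climatology shaped for ~54.5° N, 18–235 W m⁻²).
Attenuation comes from Secchi depth via the Poole–Atkins reciprocal
`k = C/SD` with `C = 1.7`; the constant is exposed in the configuration
because its appropriate value varies between water bodies. Beer's law is
evaluated at `z = max(d − 0.5, 0)` — the clamp covers cells shallower
than the canopy offset, for which the surface value is used. No surface
reflection or roughness correction is applied by default (plane-surface
simplification, a known slight overestimate; a `reflection` argument
exists for sensitivity work). Because the climatology is spatially
constant and attenuation is constant within a year, the monthly mean
commutes with Beer's law, which the field function exploits:
`PFD_year = mean(PFD_surface) · e^(−k z)`.

**Waves.** Each year's sea state (significant wave height H_m0) is
converted to the largest individual wave expected among N = 1000
Rayleigh-distributed waves, `H_max = 1.86 · H_m0` (the factor is
`sqrt(ln N / 2)` rounded to the quoted precision, asserted at
construction), then capped by depth-limited breaking, `H_max ≤ d`. The
cap is applied **before** the empirical period relation
`T_Hmax = 0.83 H_max + 3.17`, on the reasoning that the breaking
criterion constrains the physical wave that carries the period. The
dispersion relation `L = (g T²/2π) tanh(2π d / L)` is solved to an
absolute residual below 10⁻⁶ m by a damped fixed-point iteration seeded
at the deep-water wavelength (damping ½, at most 200 iterations), with
bisection on `[10⁻³, g T²/2π]` as a fallback for any element that fails
to converge. Bottom orbital velocity is then
`U = π H / (T sinh(2π d / L))`. The slice value is the arithmetic mean
over the slice years; an upper-percentile aggregate is available as an
option, since the representative annual statistic behind projected sea
states is a modelling choice rather than a physical constant. The
sea-state mean period T_m02 is carried through the data model but unused
by default — the maximum-wave chain supplies its own period — and a
`period = "tm02"` switch supports sensitivity runs.

## The synthetic domain

The generators produce a caricature of a fetch-limited, gently sloping
coastal strip with the statistical structure the analysis needs, not a
hydrodynamic hindcast. Reference configuration (all values in
`eelgrass_config()`, every generator a pure function of its seed):

* **Bathymetry** — 100 × 80 cells of 100 m (80 km², scaled down from a
  real regional domain by an order of magnitude), mean slope 0.125 m per
  row giving 0–12.5 m of depth, smooth alongshore "bay" undulations
  (relative amplitude 0.12) and 1% multiplicative roughness. Cells with
  0 < d ≤ 12 m are in scope (~7600 cells).
* **Water clarity** — baseline Secchi depth 5 m. The abatement scenario
  (BSAP) ramps up linearly over 2012–2020 to a +1.5 m plateau; the
  business-as-usual scenario (BAU) stays at baseline apart from a
  Gaussian-in-time clarity dip (0.4 m, centred 2040, width 6 y)
  emulating the mid-century chlorophyll increase that climate change
  produces even under constant loads. Interannual noise (0.1 m
  domain-wide, 0.05 m per cell) is keyed to (seed, year) only, so both
  scenarios share identical pre-divergence years and the four baseline
  runs are scenario-independent by construction.
* **Sea state** — near-uniform H_m0 of 0.3 m (an annual-mean,
  fetch-limited figure; storm seas enter through the maximum-wave
  statistics rather than the mean), modulated alongshore by a seeded
  exposure pattern (±35%, wavelength 30 cells) representing exposed
  open-coast sections versus sheltered bays. The alongshore pattern is a
  property of the coastline: it is shared by all wave realizations of a
  seed and fixed in time. It is also statistically necessary — without
  it PFD and MOV are both near-deterministic functions of depth and
  their smooth terms are not separable (pure concurvity). The four
  realizations differ only in small linear trends (−0.05% to +0.02% of
  H_m0 per year) and noise streams, sized so that domain-mean MOV
  changes over six decades stay of order 0.01 m s⁻¹.
* **Survey** — 7150 cells sampled uniformly without replacement, each a
  Bernoulli draw from a known generating response:
  `logit p = 0.02 (min(PFD, 350) − PFD̄) + g(MOV)`, where the wave term
  `g` is a smooth decreasing curve through zero at 0.4 m s⁻¹ with slope
  −8 there, saturating at +0.8 (calm water) and −5 (violent exposure);
  the two tanh branches share the threshold slope, so the curve is C¹.
  The light term saturates at 350 μmol photons m⁻² s⁻¹ and is centred
  on the in-scope mean, which together with the wave shape puts the
  marginal prevalence near 0.5 — deliberate, since it makes prevalence
  balancing (and hence the intercept) neutral in recovery tests. An
  early clamped-linear version of `g` was abandoned: a 4-df spline
  cannot track a kink, and observed response curves are smooth anyway.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: transect spatial
autocorrelation in the survey (cells are sampled independently),
directional wave effects, fetch geometry, tides and currents,
sediment–light feedback, and any biology beyond the static response
(no heatwave mortality, dispersal limits or biotic interactions).

## The scenario pipeline

Twelve inclusive 5-year slices tile 2007–2066; the first (2007–2011) is
the baseline. The run matrix pairs every later slice with each
nutrient × wave combination while the baseline contributes one run per
wave realization: 4 + 11 × 8 = 92 runs. Per run, slice-mean predictor
fields feed the fitted model; predictor fields are cached per
(slice, scenario) pair, so shared forcing is computed once.

Summaries and their conventions:

* **Total area** is the probability-weighted sum of cell areas
  (expected area), the natural integral under the coverage reading; a
  0.5-threshold count is available as an option.
* **Area series** expand each slice's value to its five years and
  smooth with a centred 30-year running mean. For the even window the
  climatological convention is used — ±15 years with half weight on the
  two outermost — so a linear trend passes through unchanged; windows
  truncate (with weight renormalization) at the series edges.
* **Depth profiles** bin in-scope cells into 1-m bins over (0, 12] and
  report the percent change of mean coverage per bin, with the baseline
  mean floored at 10⁻⁶ to keep unoccupied bins from dividing to
  infinity; empty bins are reported as missing, not zero.
* **Ceteris-paribus attribution** reruns the matrix with one predictor
  frozen at its baseline-slice field. The share of predictor X is
  `100 × (areal change with only X varying) / (change with both varying)`,
  per scenario combination at the final slice; a both-varying change
  below 10⁻⁶ km² flags the share as undefined rather than dividing.
  The two shares need not sum to 100 — the shortfall is the interaction
  of the smooth terms on the probability scale and is reported as
  `interaction_residual`.

## Model fitting and validation choices

* **Basis**: cubic regression splines with fixed 4 effective df per
  term (`k = 5`, unpenalized), the classical `s(x, 4)` of
  regression-based distribution modelling; `df` is configurable. Knots
  are placed **evenly over each predictor's training range** rather
  than at quantiles: the MOV distribution is strongly right-skewed
  (most cells are deep and calm), and quantile knots starve the
  response transition of resolution. In recovery experiments even knots
  roughly halved the maximum probability-scale error.
* **Response curves** are the centred smooth effects on the logit
  scale with pointwise ±1.96 SE bands from the coefficient covariance;
  the probability translation adds the intercept, i.e. shows occurrence
  probability with the other predictor at its centred reference.
  "Monotone" in tests means: adjacent increments violating monotonicity
  by at most 1% of the curve's amplitude — unpenalized 4-df splines
  show O(10⁻³) wiggle on plateau segments that is numerically, not
  ecologically, meaningful.
* **Extrapolation** beyond the training predictor range is allowed
  (cubic regression splines extend linearly past their boundary knots)
  but warned about, never silently.
* **Contributions** are normalized drop-one losses of explained
  deviance — refit without each predictor, record the explained
  deviance lost, scale the losses to sum to 100%.
* **Validation**: stratified five-fold cross-validation (fold
  membership dealt at random within each class, seeded) scored by
  rank-based AUC (Mann–Whitney form, ties half-credited), with the
  conventional verbal bands (0.7 acceptable, 0.8–0.9 excellent).
  Stratification is not optional at balanced prevalence: unstratified
  resampling can produce single-class folds.
* **Serialization**: models write to self-describing JSON (basis
  description with knots and constraint transforms, coefficients,
  covariance, training metadata); the restored object rebuilds its
  design matrix from the stored knots and reproduces predictions and
  bands exactly, with no reference to the fitting data.

## Problem sizes

The reference analysis used throughout the tests and the worked example
runs a 7604-cell domain, a 7150-record survey, sixty years of forcing
for two nutrient scenarios and four wave realizations, the 92-run
matrix, and three full projection passes (unfrozen plus one per frozen
predictor) — about a minute end to end. Unit tests use a 600-cell strip
and a 96-cell toy grid where the full domain adds nothing.

```{r, eval = FALSE}
library(eelgrass)
result <- run_scenario_analysis(seed = 1)
glance(result$cv)
autoplot(result$areas)
```

## Known limitations

* The equilibrium assumption ignores recovery lags; observed systems
  respond to nutrient abatement with decadal delays, which projection
  onto slice-mean forcing cannot represent.
* Attribution shares can exceed 100% or turn negative when the
  both-varying change is small relative to either single-predictor
  change; they are reported raw, with the undefined-change flag as the
  only guard.
* The breaking cap makes very shallow cells insensitive to sea-state
  changes (the capped wave is depth-limited), so wave-scenario variance
  vanishes right at the shoreline even though wave forcing is strongest
  there.
* Probabilities are treated as exact coverage; sampling error of the
  survey propagates into the maps only through the smooth-term
  covariance, which the area summaries do not currently carry.
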