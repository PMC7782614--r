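# eelgrass

Scenario projection of eelgrass (*Zostera marina*) occurrence from light
and wave exposure.

Eelgrass meadows are the dominant vegetation of shallow soft-sediment
coasts in the western Baltic Sea, and their depth distribution is pinched
between two physical gradients: light starvation sets the lower depth
limit, while wave-driven bed shear sets the upper one. Nutrient
abatement programmes (such as the HELCOM Baltic Sea Action Plan, BSAP)
promise clearer water and therefore deeper light penetration — but they
will act on a coast whose wave climate is itself changing. This package
implements the full modelling chain needed to ask *where and how much*
eelgrass cover changes under combinations of nutrient scenarios and wave
climates, for coastal ecologists and marine spatial planners:

1. **Light predictor.** Photosynthetic photon flux density (PFD,
   μmol photons m⁻² s⁻¹) 0.5 m above the sea floor via Beer's law
   *I_z = I₀ e^(−kz)*, with surface PFD = 4.15 × irradiance (W m⁻²) and
   the attenuation coefficient taken from Secchi depth as *k* = 1.7/SD.
2. **Wave predictor.** Maximum orbital velocity (MOV, m s⁻¹) at the sea
   floor from linear wave theory: the maximum expected wave
   *H*max = 1.86 × *H*m0 (Rayleigh statistics, N = 1000 waves), capped
   by depth-limited breaking (*H*max ≤ *d*), with period
   *T*Hmax = 0.83 *H*max + 3.17, wavelength from the implicit dispersion
   relation *L* = (g T²/2π) tanh(2π d/L), and
   *U* = π H / (T sinh(2π d/L)).
3. **Occurrence model.** A balanced-prevalence binomial GAM (logit link,
   one fixed 4-df cubic regression spline per predictor) relating
   presence/absence survey records to PFD and MOV. Balanced prevalence
   lets the predicted probability be read directly as expected percent
   cover.
4. **Scenario pipeline.** Twelve 5-year time slices (2007–2011 baseline
   through 2062–2066), a nutrient × wave run matrix (2 nutrient
   scenarios × 4 wave realizations, 92 runs), probability maps, total
   expected area, 30-year running means, 1-m depth-bin change profiles,
   and ceteris-paribus attribution of areal change to each predictor.
5. **Synthetic domain.** Seeded generators for bathymetry, per-year
   Secchi and sea-state forcing, and Bernoulli survey records with a
   known generating response — so the whole chain is testable end to
   end, including recovery of the generating thresholds.

All user-facing functions take data frames and return tibbles; fitted
models and cross-validation results support `tidy()`/`glance()`, and the
result types have `autoplot()` methods.

## Worked example

The reference analysis — synthesize the coast, derive predictors, fit and
validate the model, project the 92-run matrix and summarise — is one
call (a few tens of seconds):

```r
library(eelgrass)
result <- run_scenario_analysis(seed = 1)

result$model
#> Balanced-prevalence occurrence GAM (binomial, logit)
#>   predictors: pfd, mov (4 df cubic regression spline each)
#>   n = 7070, prevalence = 0.500, explained deviance = 26.6%

glance(result$cv)
#> # A tibble: 1 × 5
#>       k     n auc.mean  auc.sd discrimination
#>   <dbl> <int>    <dbl>   <dbl> <chr>
#> 1     5  7070    0.823 0.00944 excellent

result$contributions
#> # A tibble: 2 × 3
#>   predictor deviance_loss contribution
#>   <chr>             <dbl>        <dbl>
#> 1 pfd                280.         71.2
#> 2 mov                113.         28.8

curve_crossing(response_curve(result$model, "mov"))
#> [1] 0.389
```

The cross-validated AUC of 0.82 means a randomly chosen presence cell is
ranked above a randomly chosen absence cell 82% of the time
("excellent" discrimination); the fitted wave response crosses 50%
occurrence probability at 0.39 m s⁻¹, recovering the 0.4 m s⁻¹
threshold the synthetic survey was generated with. Light carries 71% of
the explained deviance in this world, waves 29%.

Projected area changes between the baseline (2007–2011) and final
(2062–2066) slices, per scenario combination:

```r
#>   nutrient  wave area_km2 change_pct
#> 1      BAU A1B_1     38.1       -0.7
#> 2      BAU A1B_2     38.0       -1.1
#> 3      BAU  B1_1     37.6       -1.8
#> 4      BAU  B1_2     37.9       -1.1
#> 5     BSAP A1B_1     46.2       20.3
#> 6     BSAP A1B_2     46.1       20.0
#> 7     BSAP  B1_1     45.8       19.6
#> 8     BSAP  B1_2     46.0       20.1
```

Under business-as-usual nutrient loads the meadow area is essentially
static (within ±2%, the residual being the wave-climate trend of each
realization), while full nutrient abatement expands it by ~20%,
concentrated — as `result$depth_profiles` shows — in the 5–6 m depth
bin, where extra light converts marginal habitat. Ceteris-paribus
attribution (`result$attribution`) confirms the split: with waves frozen
at baseline, light change alone reproduces 97–101% of each BSAP run's
areal change, and the light × wave interaction residual stays below 1%.

Plots: `autoplot(response_curve(result$model, "pfd"))`,
`autoplot(result$areas)` (30-year running-mean area series),
`autoplot()` on any row-filtered depth profile, and
`plot_probability_map()` for occurrence and difference maps.

A thin command-line front end with `simulate` / `predictors` / `fit` /
`project` / `summarize` / `all` subcommands lives at
`inst/scripts/eelgrass-pipeline.R`; models serialize to self-describing
JSON (`write_sdm()`/`read_sdm()`), grids to plain-text ESRI ASCII
(`write_ascii_grid()`), and configurations to YAML (`write_config()`).

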