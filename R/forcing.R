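#' Nutrient-scenario and wave-realization labels
#'
#' The nutrient dimension distinguishes full implementation of the Baltic
#' Sea Action Plan reduction targets (`"BSAP"`) from business-as-usual
#' loads held at the 1997-2003 reference level (`"BAU"`). The wave
#' dimension carries the two greenhouse-gas emission scenarios (A1B, B1),
#' each in two realizations started from different initial conditions.
#'
#' @name scenario-labels
#' @export
nutrient_scenarios <- function() c("BSAP", "BAU")

#' @rdname scenario-labels
#' @export
wave_realizations <- function() c("A1B_1", "A1B_2", "B1_1", "B1_2")

#' Generate per-year Secchi-depth fields for a nutrient scenario
#'
#' Emulates the water-clarity trajectory of a biogeochemical projection at
#' field level. Under `BSAP`, Secchi depth ramps up linearly over the
#' 2012-2020 nutrient-reduction phase-in and plateaus at
#' `baseline_secchi + improvement` from 2021 on. Under `BAU`, the mean
#' stays at the baseline but a Gaussian-in-time clarity dip of amplitude
#' `oscillation` centred on `oscillation_year` emulates the mid-century
#' chlorophyll increase that climate forcing alone produces. Interannual
#' noise is seeded per year *independently of the scenario label*, so the
#' two scenarios are identical over years before the 2012 divergence.
#'
#' @param grid A `depth_grid`; fields are produced for in-scope cells only.
#' @param nutrient_scenario `"BSAP"` or `"BAU"`.
#' @param years Integer years, within 2007-2066.
#' @param baseline_secchi Baseline Secchi depth, m.
#' @param improvement BSAP clarity gain at full implementation, m.
#' @param ramp_years Two years bracketing the linear load-reduction ramp;
#'   the improvement is 0 up to `ramp_years[1] - 1` and complete at
#'   `ramp_years[2] + 1`.
#' @param oscillation,oscillation_year,oscillation_width Amplitude (m),
#'   centre year, and Gaussian width (years) of the BAU mid-century
#'   clarity dip.
#' @param year_noise_sd,cell_noise_sd Standard deviations (m) of the
#'   domain-wide interannual and cell-level Secchi noise.
#' @param seed Integer seed.
#' @return A tibble with columns `row`, `col`, `year`, `secchi` (m),
#'   attribute `nutrient_scenario`; one record per in-scope cell and year.
#' @examples
#' grid <- make_bathymetry(n_rows = 12, n_cols = 6, slope = 1, seed = 1)
#' sd_bsap <- make_secchi_series(grid, "BSAP", years = 2007:2026, seed = 1)
#' @export
make_secchi_series <- function(grid, nutrient_scenario, years = 2007:2066,
                               baseline_secchi = 5, improvement = 1.5,
                               ramp_years = c(2012, 2020),
                               oscillation = 0.4, oscillation_year = 2040,
                               oscillation_width = 6,
                               year_noise_sd = 0.1, cell_noise_sd = 0.05,
                               seed = 1L) {
  nutrient_scenario <- match.arg(nutrient_scenario, nutrient_scenarios())
  check_years(years)

  cells <- dplyr::filter(grid, .data$in_scope)
  n_cell <- nrow(cells)

  per_year <- purrr::map(years, function(y) {
    mean_sd <- baseline_secchi
    if (nutrient_scenario == "BSAP") {
      frac <- (y - (ramp_years[1] - 1)) / (ramp_years[2] + 1 - (ramp_years[1] - 1))
      mean_sd <- mean_sd + improvement * min(max(frac, 0), 1)
    } else {
      mean_sd <- mean_sd -
        oscillation * exp(-((y - oscillation_year) / oscillation_width)^2)
    }
    # noise stream keyed by (seed, year) only: scenarios share pre-ramp years
    noise <- with_seed(seed * 1000L + (y - 2000L), {
      rnorm(1L, 0, year_noise_sd) + rnorm(n_cell, 0, cell_noise_sd)
    })
    if (year_noise_sd == 0 && cell_noise_sd == 0) noise <- 0
    tibble::tibble(
      row = cells$row, col = cells$col, year = y,
      secchi = pmax(mean_sd + noise, 0.2)
    )
  })
  out <- dplyr::bind_rows(per_year)
  attr(out, "nutrient_scenario") <- nutrient_scenario
  out
}

#' Generate per-year sea-state fields for a wave realization
#'
#' Emulates a long-term wave projection at field level: significant wave
#' height `hm0` is a base sea state times an offshore-exposure index times
#' a realization-specific linear trend, plus seeded interannual noise; the
#' mean period `tm02` follows `hm0` through a monotone linear relation.
#' Realizations differ only in trend sign/magnitude and noise stream. The
#' default trends are small (fractions of a percent per year) so that
#' domain-mean orbital-velocity changes over six decades stay of order
#' 0.01 m s^-1, the magnitude coastal wave projections report.
#'
#' @inheritParams make_secchi_series
#' @param wave_realization One of [wave_realizations()].
#' @param base_hm0 Domain base significant wave height, m.
#' @param exposure_range Two numbers: the exposure index rises from
#'   `exposure_range[1]` at the shoreline towards `exposure_range[2]`
#'   offshore (saturating in a few depth-scale lengths). Equal values give
#'   a spatially uniform sea state, the fetch-limited default.
#' @param trends Named per-year relative `hm0` trends, one per realization.
#' @param alongshore_amplitude,alongshore_wavelength Relative amplitude
#'   and wavelength (cells) of the alongshore exposure pattern: smooth
#'   seeded undulations emulating exposed open-coast sections versus
#'   sheltered bays. The pattern is a property of the coastline, so it is
#'   shared by all realizations of the same seed and held fixed in time.
#'   Without it both predictors would be near-deterministic functions of
#'   depth alone and their effects would not be separable.
#' @param tm02_intercept,tm02_slope Linear `tm02 = a + b * hm0` relation
#'   (s, s/m).
#' @param year_noise_sd Relative standard deviation of the domain-wide
#'   interannual `hm0` factor.
#' @return A tibble with columns `row`, `col`, `year`, `hm0` (m),
#'   `tm02` (s), attribute `wave_realization`.
#' @export
make_wave_series <- function(grid, wave_realization, years = 2007:2066,
                             base_hm0 = 0.3, exposure_range = c(1, 1),
                             trends = c(A1B_1 = -5e-4, A1B_2 = -3e-4,
                                        B1_1 = 2e-4, B1_2 = -5e-5),
                             alongshore_amplitude = 0.35,
                             alongshore_wavelength = 30,
                             tm02_intercept = 2.6, tm02_slope = 1.6,
                             year_noise_sd = 0.02, seed = 1L) {
  wave_realization <- match.arg(wave_realization, wave_realizations())
  check_years(years)
  trend <- trends[[wave_realization]]
  realization_index <- match(wave_realization, wave_realizations())

  cells <- dplyr::filter(grid, .data$in_scope)
  exposure <- exposure_range[1] +
    (exposure_range[2] - exposure_range[1]) * tanh(cells$depth / 4)
  if (alongshore_amplitude > 0) {
    phases <- with_seed(seed * 1000L + 7L, runif(2L, 0, 2 * pi))
    along <- cells$col / alongshore_wavelength
    exposure <- exposure * pmax(
      1 + alongshore_amplitude * (0.7 * sin(2 * pi * along + phases[1L]) +
                                    0.3 * sin(4 * pi * along + phases[2L])),
      0.2
    )
  }

  per_year <- purrr::map(years, function(y) {
    factor_trend <- 1 + trend * (y - years[1])
    noise <- if (year_noise_sd > 0) {
      with_seed(seed * 1000L + realization_index * 101L + (y - 2000L),
                rnorm(1L, 0, year_noise_sd))
    } else {
      0
    }
    hm0 <- pmax(base_hm0 * exposure * factor_trend * (1 + noise), 0)
    tibble::tibble(
      row = cells$row, col = cells$col, year = y,
      hm0 = hm0, tm02 = tm02_intercept + tm02_slope * hm0
    )
  })
  out <- dplyr::bind_rows(per_year)
  attr(out, "wave_realization") <- wave_realization
  out
}

check_years <- function(years) {
  if (length(years) == 0 || any(years < 2007) || any(years > 2066)) {
    abort("`years` must lie within 2007-2066.")
  }
  invisible(years)
}

#' Full scenario forcing for the run matrix
#'
#' Convenience wrapper generating the Secchi series for every nutrient
#' scenario and the sea-state series for every wave realization, as
#' consumed by [run_projection()].
#'
#' @inheritParams make_secchi_series
#' @param ... Passed on to [make_secchi_series()] and [make_wave_series()]
#'   (arguments are matched to whichever generator accepts them).
#' @return A list with elements `secchi` (named list per nutrient
#'   scenario) and `waves` (named list per wave realization).
#' @export
make_scenario_forcing <- function(grid, years = 2007:2066, seed = 1L, ...) {
  dots <- list(...)
  secchi_args <- dots[names(dots) %in% names(formals(make_secchi_series))]
  wave_args <- dots[names(dots) %in% names(formals(make_wave_series))]
  list(
    secchi = purrr::map(
      rlang::set_names(nutrient_scenarios()),
      function(ns) {
        do.call(make_secchi_series,
                c(list(grid = grid, nutrient_scenario = ns, years = years,
                       seed = seed), secchi_args))
      }
    ),
    waves = purrr::map(
      rlang::set_names(wave_realizations()),
      function(wr) {
        do.call(make_wave_series,
                c(list(grid = grid, wave_realization = wr, years = years,
                       seed = seed), wave_args))
      }
    )
  )
}
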