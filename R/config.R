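#' Default analysis configuration
#'
#' One nested list holding every generator parameter, model setting and
#' seed of the analysis, overridable piecewise and round-trippable
#' through YAML ([read_config()], [write_config()]). The defaults define
#' the package's reference synthetic study: an 80 km^2 coastal strip on a
#' 100 m grid with depths to 12.5 m, a 5 m baseline Secchi depth gaining
#' 1.5 m under nutrient abatement, a near-uniform ~0.3 m significant
#' wave height with small realization-specific trends, and a 7150-record
#' presence/absence survey.
#'
#' @param ... Named overrides; nested lists are merged element-wise
#'   (e.g. `grid = list(n_rows = 50)` changes only that entry).
#' @return A nested configuration list of class `eelgrass_config`.
#' @examples
#' cfg <- eelgrass_config(survey = list(n = 1000))
#' cfg$survey$n
#' @export
eelgrass_config <- function(...) {
  defaults <- list(
    seed = 1L,
    grid = list(
      n_rows = 100, n_cols = 80, cell_size = 100, slope = 0.125,
      bay_amplitude = 0.12, bay_wavelength = 25, roughness = 0.01,
      max_depth_in_scope = 12
    ),
    light = list(
      secchi_constant = 1.7, canopy_offset = 0.5, reflection = 0,
      months = 1:12,
      irradiance = c(25, 55, 105, 165, 220, 235, 225, 190, 130, 70, 30, 18)
    ),
    secchi = list(
      baseline_secchi = 5, improvement = 1.5, ramp_years = c(2012, 2020),
      oscillation = 0.4, oscillation_year = 2040, oscillation_width = 6,
      year_noise_sd = 0.1, cell_noise_sd = 0.05
    ),
    waves = list(
      base_hm0 = 0.3, exposure_range = c(1, 1),
      trends = c(A1B_1 = -5e-4, A1B_2 = -3e-4, B1_1 = 2e-4, B1_2 = -5e-5),
      tm02_intercept = 2.6, tm02_slope = 1.6, year_noise_sd = 0.02
    ),
    survey = list(
      n = 7150, years = c(2010, 2011),
      truth = list(
        beta0 = 0, pfd_slope = 0.02, pfd_sat = 350, mov_slope = 8,
        mov_threshold = 0.4, mov_max_effect = 0.8, mov_min_effect = 5
      )
    ),
    model = list(df = 4, cv_folds = 5),
    period = list(start = 2007, end = 2066, width = 5),
    area = list(method = "expected", threshold = 0.5)
  )
  structure(merge_config(defaults, list(...)), class = "eelgrass_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a configuration as YAML
#'
#' @param config An `eelgrass_config`.
#' @param path YAML file path.
#' @return `read_config()` returns an `eelgrass_config` (file entries
#'   override package defaults); `write_config()` returns `path`
#'   invisibly.
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  # yaml drops names of atomic vectors; keep the trend names as a map
  if (!is.null(raw$waves$trends)) {
    raw$waves$trends <- as.list(raw$waves$trends)
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$waves$trends)) {
    raw$waves$trends <- unlist(raw$waves$trends)
  }
  do.call(eelgrass_config, raw)
}

#' Run the full scenario analysis
#'
#' End-to-end orchestration of the reference analysis: synthesize the
#' bathymetry and scenario forcing, derive baseline predictors, sample
#' and balance the survey, fit and cross-validate the occurrence model,
#' project the full nutrient-by-wave run matrix, and summarise areas,
#' depth-binned change and ceteris-paribus attribution.
#'
#' @param config An [eelgrass_config()].
#' @param seed Overrides `config$seed` if given.
#' @param stages Which stages to run: the projection stage dominates the
#'   runtime; `summarise` implies `project`.
#' @return A list with (depending on stages) `grid`, `forcing`,
#'   `observations`, `sample`, `model`, `cv`, `contributions`,
#'   `projection`, `areas`, `depth_profiles` and `attribution`.
#' @export
run_scenario_analysis <- function(config = eelgrass_config(), seed = NULL,
                                  stages = c("fit", "project", "summarise")) {
  seed <- as.integer(seed %||% config$seed)
  grid <- do.call(make_bathymetry, c(config$grid, list(seed = seed)))

  years <- seq(config$period$start, config$period$end)
  forcing <- list(
    secchi = purrr::map(
      rlang::set_names(nutrient_scenarios()),
      ~ do.call(make_secchi_series,
                c(list(grid = grid, nutrient_scenario = .x, years = years,
                       seed = seed), config$secchi))
    ),
    waves = purrr::map(
      rlang::set_names(wave_realizations()),
      ~ do.call(make_wave_series,
                c(list(grid = grid, wave_realization = .x, years = years,
                       seed = seed), config$waves))
    )
  )

  slices <- do.call(make_time_slices, config$period)
  baseline_years <- seq(slices$start_year[1], slices$end_year[1])
  irradiance <- irradiance_climatology(config$light$irradiance)

  pfd0 <- pfd_predictor_field(
    forcing$secchi[[1]], grid, baseline_years, irradiance = irradiance,
    months = config$light$months,
    secchi_constant = config$light$secchi_constant,
    canopy_offset = config$light$canopy_offset,
    reflection = config$light$reflection
  )
  mov0 <- mov_predictor_field(forcing$waves[[1]], grid, baseline_years)

  truth <- do.call(occurrence_truth, config$survey$truth)
  observations <- sample_observations(
    grid, pfd0, mov0, truth = truth, n = config$survey$n,
    survey_years = config$survey$years, seed = seed + 1L
  )
  sample <- balance_prevalence(observations, seed = seed + 2L)
  model <- fit_occurrence_gam(sample, df = config$model$df)

  out <- list(
    config = config, seed = seed, grid = grid, forcing = forcing,
    observations = observations, sample = sample, model = model,
    cv = crossvalidate_auc(sample, k = config$model$cv_folds,
                           seed = seed + 3L, df = config$model$df),
    contributions = predictor_contributions(model),
    baseline_predictors = list(pfd = pfd0, mov = mov0)
  )
  if (!any(c("project", "summarise") %in% stages)) return(out)

  plan <- enumerate_runs(slices)
  out$plan <- plan
  out$projection <- run_projection(
    model, grid, forcing, plan, irradiance = irradiance,
    months = config$light$months,
    secchi_constant = config$light$secchi_constant,
    area_method = config$area$method, area_threshold = config$area$threshold
  )
  if (!"summarise" %in% stages) return(out)

  out$areas <- area_series(out$projection)

  final_slice <- max(plan$slice)
  combos <- dplyr::filter(plan, .data$slice == final_slice)
  out$depth_profiles <- purrr::pmap(
    combos[c("run", "nutrient", "wave")],
    function(run, nutrient, wave) {
      base_run <- plan$run[plan$slice == 1 & plan$wave == wave]
      profile <- depth_binned_change(
        projection_map(out$projection, base_run),
        projection_map(out$projection, run), grid
      )
      dplyr::mutate(profile, nutrient = nutrient, wave = wave,
                    .before = 1)
    }
  )
  out$depth_profiles <- dplyr::bind_rows(out$depth_profiles)

  out$attribution <- predictor_attribution(
    model, grid, forcing, plan, full = out$projection,
    irradiance = irradiance,
    months = config$light$months,
    secchi_constant = config$light$secchi_constant
  )
  out
}
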