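#' Tile a study period into 5-year time slices
#'
#' The projection period 2007-2066 is tiled into twelve consecutive
#' inclusive 5-year slices: 2007-2011 (the baseline), 2012-2016, ...,
#' 2062-2066. Predictor fields are averaged within each slice.
#'
#' @param start,end First and last year, inclusive.
#' @param width Slice width in years; `end - start + 1` must be a
#'   multiple of it.
#' @return A tibble `slice`, `start_year`, `end_year`, `label`.
#' @examples
#' make_time_slices() # twelve slices, 2007-2011 ... 2062-2066
#' @export
make_time_slices <- function(start = 2007, end = 2066, width = 5) {
  span <- end - start + 1
  if (span <= 0 || span %% width != 0) {
    abort("`end - start + 1` must be a positive multiple of `width`.")
  }
  starts <- seq(start, end, by = width)
  tibble::tibble(
    slice = seq_along(starts),
    start_year = starts,
    end_year = starts + width - 1,
    label = paste0(starts, "-", starts + width - 1)
  )
}

#' Enumerate the scenario run matrix
#'
#' The baseline (first) slice predates the divergence of the nutrient
#' scenarios, so it contributes one run per wave realization only; every
#' later slice contributes one run per nutrient-by-wave combination. With
#' twelve slices, two nutrient scenarios and four wave realizations this
#' yields 4 + 11 x 8 = 92 runs. Ordering is deterministic:
#' (slice, nutrient, wave).
#'
#' @param slices A tibble from [make_time_slices()].
#' @param nutrients Character vector of nutrient scenarios.
#' @param waves Character vector of wave realizations.
#' @return A `run_plan` tibble: `run`, `slice`, `start_year`, `end_year`,
#'   `nutrient` (`"BASELINE"` on the first slice), `wave`.
#' @examples
#' nrow(enumerate_runs(make_time_slices())) # 92
#' @export
enumerate_runs <- function(slices, nutrients = nutrient_scenarios(),
                           waves = wave_realizations()) {
  if (length(nutrients) == 0 || length(waves) == 0) {
    abort("Scenario lists must be non-empty.")
  }
  base_slice <- slices[1, ]
  base <- tidyr::expand_grid(
    slice = base_slice$slice, nutrient = "BASELINE", wave = waves
  )
  future <- if (nrow(slices) > 1) {
    tidyr::expand_grid(
      slice = slices$slice[-1], nutrient = nutrients, wave = waves
    )
  } else {
    NULL
  }
  plan <- dplyr::bind_rows(base, future)
  plan <- dplyr::left_join(
    plan, dplyr::select(slices, "slice", "start_year", "end_year"),
    by = "slice"
  )
  plan <- dplyr::arrange(plan, .data$slice, .data$nutrient, .data$wave)
  tibble::tibble(
    run = seq_len(nrow(plan)),
    plan[c("slice", "start_year", "end_year", "nutrient", "wave")]
  )
}

#' Project occurrence maps over the scenario run matrix
#'
#' For every run of the plan, derives the slice-mean light and
#' wave-exposure predictor fields from the scenario forcing
#' ([pfd_predictor_field()], [mov_predictor_field()]), evaluates the
#' fitted occurrence model, and collects the per-cell probability maps
#' and per-run expected areas. Predictor fields are cached per
#' (slice, scenario) pair, so the four baseline runs share nutrient
#' forcing by construction. Ceteris-paribus runs freeze one predictor at
#' its baseline-slice field via `freeze`.
#'
#' @param model An `eelgrass_sdm`.
#' @param grid A `depth_grid`.
#' @param forcing A list with `secchi` (per nutrient scenario) and
#'   `waves` (per wave realization), as from [make_scenario_forcing()].
#' @param plan A `run_plan` from [enumerate_runs()].
#' @param irradiance,months,secchi_constant Passed to
#'   [pfd_predictor_field()].
#' @param constants,period Passed to [mov_predictor_field()].
#' @param freeze `NULL`, `"pfd"`, `"mov"`, or both: predictors to hold at
#'   their baseline-slice field in every run.
#' @param area_method,area_threshold Passed to [total_area()].
#' @return An `eelgrass_projection`: list with `maps` (tibble `run`,
#'   `row`, `col`, `probability`), `areas` (the plan plus `area_km2`),
#'   `plan`, and `frozen`.
#' @export
run_projection <- function(model, grid, forcing, plan,
                           irradiance = irradiance_climatology(),
                           months = 1:12, secchi_constant = 1.7,
                           constants = wave_constants(),
                           period = "thmax", freeze = NULL,
                           area_method = "expected",
                           area_threshold = 0.5) {
  if (!is.null(freeze)) {
    freeze <- match.arg(freeze, c("pfd", "mov"), several.ok = TRUE)
  }
  slices <- dplyr::distinct(
    plan, .data$slice, .data$start_year, .data$end_year
  )
  years_of <- function(s) {
    row <- slices[slices$slice == s, ]
    seq(row$start_year, row$end_year)
  }
  baseline_slice <- min(plan$slice)
  first_nutrient <- names(forcing$secchi)[1]

  pfd_cache <- new.env(parent = emptyenv())
  pfd_for <- function(slice, nutrient) {
    if (nutrient == "BASELINE") nutrient <- first_nutrient
    if ("pfd" %in% freeze) slice <- baseline_slice
    key <- paste(slice, nutrient)
    if (is.null(pfd_cache[[key]])) {
      pfd_cache[[key]] <- pfd_predictor_field(
        forcing$secchi[[nutrient]], grid, years_of(slice),
        irradiance = irradiance, months = months,
        secchi_constant = secchi_constant
      )
    }
    pfd_cache[[key]]
  }
  mov_cache <- new.env(parent = emptyenv())
  mov_for <- function(slice, wave) {
    if ("mov" %in% freeze) slice <- baseline_slice
    key <- paste(slice, wave)
    if (is.null(mov_cache[[key]])) {
      mov_cache[[key]] <- mov_predictor_field(
        forcing$waves[[wave]], grid, years_of(slice),
        constants = constants, period = period
      )
    }
    mov_cache[[key]]
  }

  maps <- purrr::map(seq_len(nrow(plan)), function(i) {
    r <- plan[i, ]
    map <- suppressWarnings(predict_probability(
      model, pfd_for(r$slice, r$nutrient), mov_for(r$slice, r$wave)
    ))
    map$run <- r$run
    map
  })
  maps <- dplyr::bind_rows(maps)[c("run", "row", "col", "probability")]

  areas <- dplyr::mutate(
    plan,
    area_km2 = purrr::map_dbl(.data$run, function(id) {
      total_area(maps[maps$run == id, ], grid,
                 method = area_method, threshold = area_threshold)
    })
  )
  structure(
    list(maps = maps, areas = areas, plan = plan,
         frozen = freeze %||% character(0)),
    class = "eelgrass_projection"
  )
}

#' @export
print.eelgrass_projection <- function(x, ...) {
  cat(sprintf("Scenario projection: %d runs over %d slices",
              nrow(x$plan), length(unique(x$plan$slice))))
  if (length(x$frozen) > 0) {
    cat(sprintf(" (frozen: %s)", paste(x$frozen, collapse = ", ")))
  }
  cat("\n")
  cat(sprintf("  area range %.1f - %.1f km^2\n",
              min(x$areas$area_km2), max(x$areas$area_km2)))
  invisible(x)
}

#' Extract one probability map from a projection
#'
#' @param projection An `eelgrass_projection`.
#' @param run Run id (see the projection's `plan`).
#' @return A tibble `row`, `col`, `probability`.
#' @export
projection_map <- function(projection, run) {
  m <- projection$maps[projection$maps$run == run, ]
  if (nrow(m) == 0) abort("No such run in the projection.")
  m[c("row", "col", "probability")]
}

#' Cellwise difference of two occurrence maps
#'
#' @param final,baseline Probability maps (tibbles `row`, `col`,
#'   `probability`) on the same cells.
#' @return A tibble `row`, `col`, `delta` with `delta` in `[-1, 1]`.
#' @export
difference_map <- function(final, baseline) {
  if (nrow(final) != nrow(baseline)) {
    abort("Maps are not congruent.")
  }
  joined <- dplyr::inner_join(final, baseline, by = c("row", "col"),
                              suffix = c("_final", "_baseline"))
  if (nrow(joined) != nrow(final)) abort("Maps are not congruent.")
  tibble::tibble(
    row = joined$row, col = joined$col,
    delta = joined$probability_final - joined$probability_baseline
  )
}

#' Total eelgrass area of a probability map
#'
#' With balanced-prevalence training the occurrence probability reads as
#' expected coverage, so the default area is the probability-weighted sum
#' of cell areas. `method = "threshold"` counts cells above a cutoff
#' instead.
#'
#' @param map A probability map (`row`, `col`, `probability`).
#' @param grid The `depth_grid` the map lives on (supplies cell size).
#' @param method `"expected"` (default) or `"threshold"`.
#' @param threshold Cutoff used by the threshold method.
#' @return Area in km^2.
#' @examples
#' # 100 cells of 100 m at p = 0.5 -> 0.5 km^2
#' @export
total_area <- function(map, grid, method = c("expected", "threshold"),
                       threshold = 0.5) {
  method <- match.arg(method)
  p <- map$probability
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  cell_km2 <- attr(grid, "cell_size")^2 / 1e6
  if (method == "expected") {
    sum(p) * cell_km2
  } else {
    sum(p >= threshold) * cell_km2
  }
}

#' Centred 30-year running mean
#'
#' Smooths an annual series with a symmetric centred moving window,
#' truncated at the series edges (the weighted mean is taken over the
#' window years that exist). For an even width the climatological
#' convention is used: the window spans `window/2` years on either side
#' with half weight on the two outermost years, so the total weight is
#' `window` and a linear trend passes through unchanged.
#'
#' @param x Numeric annual series (or a vector of slice values already
#'   expanded to years).
#' @param window Window width in years (default 30).
#' @return Numeric vector, same length as `x`.
#' @export
running_mean_30y <- function(x, window = 30) {
  n <- length(x)
  if (n == 0) abort("Series is empty.")
  if (window %% 2 == 0) {
    h <- window / 2
    w <- c(0.5, rep(1, window - 1), 0.5)
  } else {
    h <- (window - 1) / 2
    w <- rep(1, window)
  }
  offsets <- -h:h
  vapply(seq_len(n), function(i) {
    j <- i + offsets
    ok <- j >= 1 & j <= n
    sum(w[ok] * x[j[ok]]) / sum(w[ok])
  }, numeric(1))
}

#' Annual area series with 30-year running means
#'
#' Expands per-run slice areas to an annual series (each year inherits
#' its slice's value), per scenario combination, and attaches the centred
#' 30-year running mean and the percent change relative to the baseline
#' area of the same wave realization.
#'
#' @param projection An `eelgrass_projection` from [run_projection()].
#' @param window Running-mean window, years.
#' @return An `area_series` tibble: `nutrient`, `wave`, `year`,
#'   `area_km2`, `area_smoothed`, `percent_change`.
#' @export
area_series <- function(projection, window = 30) {
  areas <- projection$areas
  base <- areas[areas$nutrient == "BASELINE", ]
  future_nutrients <- setdiff(unique(areas$nutrient), "BASELINE")
  combos <- tidyr::expand_grid(
    nutrient = future_nutrients, wave = unique(areas$wave)
  )
  out <- purrr::pmap(combos, function(nutrient, wave) {
    runs <- areas[(areas$nutrient == nutrient | areas$nutrient == "BASELINE") &
                    areas$wave == wave, ]
    runs <- dplyr::arrange(runs, .data$slice)
    annual <- tidyr::unnest(
      dplyr::mutate(
        runs,
        year = purrr::map2(.data$start_year, .data$end_year, seq)
      ),
      "year"
    )
    base_area <- base$area_km2[base$wave == wave]
    tibble::tibble(
      nutrient = nutrient, wave = wave, year = annual$year,
      area_km2 = annual$area_km2,
      area_smoothed = running_mean_30y(annual$area_km2, window),
      percent_change = 100 * (annual$area_km2 - base_area) / base_area
    )
  })
  structure(
    dplyr::bind_rows(out),
    class = c("area_series", class(tibble::tibble()))
  )
}

#' Depth-binned coverage change profile
#'
#' Assigns in-scope cells to depth bins of `bin_width` metres over
#' (0, 12] and reports, per bin, the percent change of mean coverage
#' between a baseline and a final map:
#' `100 * (mean_final - mean_baseline) / max(mean_baseline, eps)`.
#' Bins containing no cells are kept with `NA` change.
#'
#' @param baseline,final Probability maps on the grid's in-scope cells.
#' @param grid A `depth_grid`.
#' @param bin_width Bin width, m (default 1).
#' @param eps Denominator floor guarding unoccupied bins.
#' @return A `depth_profile` tibble: `bin_lower`, `bin_upper`, `n_cells`,
#'   `mean_baseline`, `mean_final`, `percent_change`.
#' @export
depth_binned_change <- function(baseline, final, grid, bin_width = 1,
                                eps = 1e-6) {
  max_d <- attr(grid, "max_depth_in_scope")
  breaks <- seq(0, max_d, by = bin_width)
  diff <- difference_map(final, baseline)
  cells <- dplyr::inner_join(
    dplyr::inner_join(
      baseline,
      dplyr::select(dplyr::filter(grid, .data$in_scope),
                    "row", "col", "depth"),
      by = c("row", "col")
    ),
    dplyr::rename(final, probability_final = "probability"),
    by = c("row", "col")
  )
  cells$bin <- cut(cells$depth, breaks = breaks, right = TRUE)
  binned <- dplyr::summarise(
    dplyr::group_by(cells, .data$bin, .drop = FALSE),
    n_cells = dplyr::n(),
    mean_baseline = mean(.data$probability),
    mean_final = mean(.data$probability_final),
    .groups = "drop"
  )
  binned <- binned[!is.na(binned$bin), ]
  structure(
    tibble::tibble(
      bin_lower = breaks[-length(breaks)],
      bin_upper = breaks[-1],
      n_cells = binned$n_cells,
      mean_baseline = binned$mean_baseline,
      mean_final = binned$mean_final,
      percent_change = ifelse(
        binned$n_cells == 0, NA_real_,
        100 * (binned$mean_final - binned$mean_baseline) /
          pmax(binned$mean_baseline, eps)
      )
    ),
    class = c("depth_profile", class(tibble::tibble()))
  )
}

#' Ceteris-paribus attribution of areal change
#'
#' Reruns the projection with one predictor frozen at its baseline-slice
#' field, so that only the other predictor varies, and attributes the
#' total areal change per scenario combination:
#' `share of X = 100 * (change with only X varying) / (change with both varying)`.
#' A both-varying total change below `min_change` km^2 makes shares
#' ill-defined; such rows are flagged with `NA` shares rather than
#' divided through.
#'
#' @inheritParams run_projection
#' @param frozen The predictor to hold at baseline (`"pfd"` or `"mov"`);
#'   the returned share belongs to the *other*, still-varying predictor.
#' @param full Optional precomputed unfrozen projection (saves recomputing
#'   it when attributing both predictors).
#' @param min_change Absolute change (km^2) below which shares are `NA`.
#' @param ... Passed to [run_projection()].
#' @return An `attribution` tibble: per (nutrient, wave) combination of
#'   the final slice, `varying`, `change_full_km2`, `change_partial_km2`,
#'   `share` (%).
#' @export
ceteris_paribus <- function(model, grid, forcing, plan,
                            frozen = c("pfd", "mov"), full = NULL,
                            min_change = 1e-6, ...) {
  frozen <- match.arg(frozen)
  varying <- setdiff(c("pfd", "mov"), frozen)
  if (is.null(full)) {
    full <- run_projection(model, grid, forcing, plan, ...)
  }
  partial <- run_projection(model, grid, forcing, plan, freeze = frozen, ...)

  change_table <- function(projection) {
    areas <- projection$areas
    base <- areas[areas$slice == min(areas$slice), ]
    final <- areas[areas$slice == max(areas$slice), ]
    final$change_km2 <- final$area_km2 -
      base$area_km2[match(final$wave, base$wave)]
    final[c("nutrient", "wave", "change_km2")]
  }
  full_chg <- change_table(full)
  part_chg <- change_table(partial)
  joined <- dplyr::inner_join(full_chg, part_chg,
                              by = c("nutrient", "wave"),
                              suffix = c("_full", "_partial"))
  structure(
    tibble::tibble(
      nutrient = joined$nutrient, wave = joined$wave, varying = varying,
      change_full_km2 = joined$change_km2_full,
      change_partial_km2 = joined$change_km2_partial,
      share = ifelse(abs(joined$change_km2_full) < min_change, NA_real_,
                     100 * joined$change_km2_partial /
                       joined$change_km2_full)
    ),
    class = c("attribution", class(tibble::tibble()))
  )
}

#' Attribute areal change to both predictors
#'
#' Convenience wrapper running the unfrozen projection once and the two
#' ceteris-paribus projections (PFD frozen, MOV frozen), returning one
#' row per scenario combination with the share of the total areal change
#' carried by each predictor and the interaction residual
#' (`100 - share_pfd - share_mov`).
#'
#' @inheritParams ceteris_paribus
#' @return A tibble `nutrient`, `wave`, `change_full_km2`, `share_pfd`,
#'   `share_mov`, `interaction_residual`.
#' @export
predictor_attribution <- function(model, grid, forcing, plan, full = NULL,
                                  ...) {
  full <- full %||% run_projection(model, grid, forcing, plan, ...)
  pfd_only <- ceteris_paribus(model, grid, forcing, plan, frozen = "mov",
                              full = full, ...)
  mov_only <- ceteris_paribus(model, grid, forcing, plan, frozen = "pfd",
                              full = full, ...)
  tibble::tibble(
    nutrient = pfd_only$nutrient, wave = pfd_only$wave,
    change_full_km2 = pfd_only$change_full_km2,
    share_pfd = pfd_only$share,
    share_mov = mov_only$share,
    interaction_residual = 100 - pfd_only$share - mov_only$share
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
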