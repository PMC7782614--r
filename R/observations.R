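#' Generating truth for synthetic surveys
#'
#' Parameterises the occurrence response used to simulate presence/absence
#' records, so that model fits can be checked against a known truth. On
#' the logit scale the occurrence probability is
#' `beta0 + pfd_slope * (min(PFD, pfd_sat) - pfd_center) + g(MOV)` where
#' the wave term `g` is a smooth decreasing curve through zero at
#' `mov_threshold` with slope `-mov_slope` there, saturating at
#' `+mov_max_effect` in calm water and at `-mov_min_effect` under violent
#' wave exposure (two hyperbolic-tangent branches with matched slope at
#' the threshold). The light term rises linearly and saturates at
#' `pfd_sat`. With the light term at its centring value, occurrence
#' probability crosses 0.5 exactly at `mov_threshold`.
#'
#' @param beta0 Intercept on the logit scale.
#' @param pfd_slope Logit change per micromol photons m^-2 s^-1 below
#'   saturation.
#' @param pfd_sat Saturating PFD (micromol photons m^-2 s^-1).
#' @param pfd_center Centring value for the light term; `NULL` (default)
#'   centres on the mean of `min(PFD, pfd_sat)` over the cells offered to
#'   the sampler, making the smooth terms zero-centred over the sampled
#'   predictor distribution.
#' @param mov_slope Logit decline per m s^-1 around the threshold.
#' @param mov_threshold Orbital velocity at which occurrence probability
#'   crosses 0.5, m s^-1 (default 0.4).
#' @param mov_max_effect,mov_min_effect Clamp of the wave term: maximum
#'   favorable (low-exposure) and maximum unfavorable logit contribution.
#' @return An object of class `occurrence_truth`.
#' @export
occurrence_truth <- function(beta0 = 0, pfd_slope = 0.02, pfd_sat = 350,
                             pfd_center = NULL, mov_slope = 8,
                             mov_threshold = 0.4, mov_max_effect = 0.8,
                             mov_min_effect = 5) {
  structure(
    list(beta0 = beta0, pfd_slope = pfd_slope, pfd_sat = pfd_sat,
         pfd_center = pfd_center, mov_slope = mov_slope,
         mov_threshold = mov_threshold, mov_max_effect = mov_max_effect,
         mov_min_effect = mov_min_effect),
    class = "occurrence_truth"
  )
}

#' True occurrence probability under a generating truth
#'
#' @param truth An [occurrence_truth()].
#' @param pfd,mov Predictor values (vectorised).
#' @return Probability of occurrence in `[0, 1]`.
#' @export
truth_probability <- function(truth, pfd, mov) {
  center <- truth$pfd_center
  if (is.null(center)) center <- mean(pmin(pfd, truth$pfd_sat))
  light <- truth$pfd_slope * (pmin(pfd, truth$pfd_sat) - center)
  # smooth decreasing wave response: tanh branches scaled so the slope at
  # the threshold is -mov_slope on both sides (C1 at the crossing)
  scale_lo <- truth$mov_max_effect / truth$mov_slope
  scale_hi <- truth$mov_min_effect / truth$mov_slope
  excess <- mov - truth$mov_threshold
  wave <- ifelse(
    excess <= 0,
    truth$mov_max_effect * tanh(-excess / scale_lo),
    -truth$mov_min_effect * tanh(excess / scale_hi)
  )
  plogis(truth$beta0 + light + wave)
}

#' Sample synthetic presence/absence survey records
#'
#' Draws `n` distinct in-scope cells (without replacement by default) and
#' assigns each a Bernoulli presence with probability given by the
#' generating truth evaluated at that cell's baseline predictors. The
#' truth (with its resolved light-term centring value) is stored on the
#' result for parameter-recovery tests.
#'
#' @param grid A `depth_grid`.
#' @param pfd_field,mov_field Baseline predictor fields (tibbles with
#'   `row`, `col` and `pfd` / `mov`), congruent with the grid's in-scope
#'   cells.
#' @param truth An [occurrence_truth()].
#' @param n Number of records (default 7150).
#' @param survey_years Integer years the survey nominally represents
#'   (metadata only).
#' @param replace Sample cells with replacement (default `FALSE`).
#' @param seed Integer seed.
#' @return An `observation_set` tibble with columns `row`, `col`,
#'   `presence`, `pfd`, `mov` and attributes `truth` and `survey_years`.
#' @export
sample_observations <- function(grid, pfd_field, mov_field,
                                truth = occurrence_truth(), n = 7150,
                                survey_years = c(2010, 2011),
                                replace = FALSE, seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  cells <- dplyr::inner_join(
    dplyr::select(dplyr::filter(grid, .data$in_scope), "row", "col"),
    dplyr::inner_join(pfd_field, mov_field, by = c("row", "col")),
    by = c("row", "col")
  )
  if (!replace && n > nrow(cells)) {
    abort(paste0("Cannot sample ", n, " distinct cells from ",
                 nrow(cells), " in-scope cells."))
  }
  if (is.null(truth$pfd_center)) {
    truth$pfd_center <- mean(pmin(cells$pfd, truth$pfd_sat))
  }
  obs <- with_seed(seed, {
    picked <- cells[sample.int(nrow(cells), n, replace = replace), ]
    p <- truth_probability(truth, picked$pfd, picked$mov)
    picked$presence <- rbinom(n, 1L, p)
    picked
  })
  obs <- dplyr::select(obs, "row", "col", "presence", "pfd", "mov")
  structure(
    tibble::as_tibble(obs),
    truth = truth, survey_years = survey_years,
    class = c("observation_set", class(tibble::tibble()))
  )
}

#' Read / write observation records as CSV
#'
#' The on-disk format is a plain CSV with columns `row`, `col`,
#' `presence` (or `x`, `y`, `presence` for georeferenced real-survey
#' data) and optionally the predictor columns `pfd`, `mov`.
#'
#' @param obs An observation tibble.
#' @param path CSV file path.
#' @return `read_observations()` returns a tibble; `write_observations()`
#'   returns `path` invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!"presence" %in% names(df)) {
    abort("Observation file must have a `presence` column.")
  }
  if (!all(df$presence %in% c(0L, 1L))) {
    abort("`presence` must be binary (0/1).")
  }
  df
}
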