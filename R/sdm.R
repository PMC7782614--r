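#' Balance prevalence of a presence/absence sample
#'
#' Subsamples the majority class without replacement down to the minority
#' class size, so that presences and absences are equally frequent. With
#' balanced prevalence the fitted probability of occurrence can be read
#' directly as a probability of plant encounter (percent coverage).
#'
#' @param obs A tibble with a binary `presence` column and predictor
#'   columns (e.g. from [sample_observations()]).
#' @param seed Integer seed controlling the subsample.
#' @return A `balanced_sample` tibble with equal class counts and
#'   attribute `prevalence` (0.5 by construction).
#' @examples
#' obs <- tibble::tibble(presence = rep(c(1, 0), c(20, 60)),
#'                       pfd = rnorm(80), mov = rnorm(80))
#' nrow(balance_prevalence(obs, seed = 1)) # 40
#' @export
balance_prevalence <- function(obs, seed = 1L) {
  pres <- which(obs$presence == 1)
  abs_ <- which(obs$presence == 0)
  if (length(pres) == 0 || length(abs_) == 0) {
    abort("Both presence and absence records are required.")
  }
  n_min <- min(length(pres), length(abs_))
  keep <- with_seed(seed, {
    c(if (length(pres) > n_min) sample(pres, n_min) else pres,
      if (length(abs_) > n_min) sample(abs_, n_min) else abs_)
  })
  out <- obs[sort(keep), , drop = FALSE]
  structure(
    tibble::as_tibble(out),
    prevalence = mean(out$presence), truth = attr(obs, "truth"),
    class = c("balanced_sample", class(tibble::tibble()))
  )
}

#' Fit the binomial smooth-term occurrence model
#'
#' Fits a generalized additive model for presence/absence on the logit
#' link, with one cubic-regression-spline smooth of fixed effective
#' degrees of freedom per predictor (default 4 df, the classical
#' `s(x, 4)` of regression-based distribution modelling). Fitting is by
#' iteratively reweighted least squares via `mgcv::gam`.
#'
#' @param sample A `balanced_sample` (or any tibble with `presence` and
#'   the predictor columns).
#' @param predictors Character vector of predictor column names (default
#'   `c("pfd", "mov")`).
#' @param df Effective degrees of freedom per smooth term (fixed, not
#'   penalized away).
#' @return An `eelgrass_sdm` object: the mgcv fit plus training metadata
#'   (predictor ranges, prevalence, generating truth if the sample
#'   carries one). Supports [predict_probability()], [response_curve()],
#'   [predictor_contributions()], [tidy()] and [glance()].
#' @export
fit_occurrence_gam <- function(sample, predictors = c("pfd", "mov"),
                               df = 4) {
  missing_cols <- setdiff(c("presence", predictors), names(sample))
  if (length(missing_cols) > 0) {
    abort(paste0("Sample lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- table(factor(sample$presence, levels = c(0, 1)))
  if (any(counts < df + 2)) {
    abort("Too few records per class to fit the smooth terms.")
  }
  for (p in predictors) {
    if (any(!is.finite(sample[[p]]))) {
      abort(paste0("Non-finite values in predictor `", p, "`."))
    }
    if (diff(range(sample[[p]])) == 0) {
      abort(paste0("Predictor `", p, "` is constant (rank deficient)."))
    }
  }
  rhs <- paste(
    sprintf("s(%s, k = %d, bs = 'cr', fx = TRUE)", predictors, df + 1),
    collapse = " + "
  )
  formula <- stats::as.formula(paste("presence ~", rhs))
  # knots spread evenly over each predictor's range: quantile-placed knots
  # cluster in the deep-water mass of skewed predictors and under-resolve
  # the response transition
  knots <- purrr::map(
    rlang::set_names(predictors),
    ~ seq(min(sample[[.x]]), max(sample[[.x]]), length.out = df + 1)
  )
  fit <- mgcv::gam(formula, family = stats::binomial(),
                   data = as.data.frame(sample), knots = knots,
                   control = mgcv::gam.control(epsilon = 1e-8))
  if (!fit$converged) abort("Occurrence model did not converge.")
  structure(
    list(
      fit = fit,
      predictors = predictors,
      df = df,
      training_ranges = purrr::map(
        rlang::set_names(predictors), ~ range(sample[[.x]])
      ),
      prevalence = mean(sample$presence),
      n = nrow(sample),
      truth = attr(sample, "truth"),
      data = tibble::as_tibble(sample)
    ),
    class = "eelgrass_sdm"
  )
}

#' @export
print.eelgrass_sdm <- function(x, ...) {
  cat("Balanced-prevalence occurrence GAM (binomial, logit)\n")
  cat(sprintf("  predictors: %s (%g df cubic regression spline each)\n",
              paste(x$predictors, collapse = ", "), x$df))
  cat(sprintf("  n = %d, prevalence = %.3f, explained deviance = %.1f%%\n",
              x$n, x$prevalence, 100 * explained_deviance(x)))
  invisible(x)
}

explained_deviance <- function(model, fit = model$fit) {
  1 - fit$deviance / fit$null.deviance
}

#' Predict occurrence probability over a grid
#'
#' Evaluates the fitted model at each in-scope cell of a predictor pair:
#' inverse-logit of intercept plus summed smooth effects. Predictor values
#' outside the training range are permitted (cubic regression splines
#' extend linearly beyond their boundary knots) but flagged with a
#' warning.
#'
#' @param model An `eelgrass_sdm`.
#' @param pfd_field,mov_field Predictor fields (tibbles with `row`,
#'   `col` and the predictor column), joined on `row`, `col`.
#' @return A tibble `row`, `col`, `probability` with values in `[0, 1]`.
#' @export
predict_probability <- function(model, pfd_field, mov_field) {
  newdata <- dplyr::inner_join(pfd_field, mov_field, by = c("row", "col"))
  for (p in model$predictors) {
    rng <- model$training_ranges[[p]]
    span <- diff(rng)
    out_frac <- mean(newdata[[p]] < rng[1] - 0.05 * span |
                       newdata[[p]] > rng[2] + 0.05 * span)
    if (out_frac > 0) {
      warn(sprintf(
        "%.1f%% of cells extrapolate `%s` beyond the training range.",
        100 * out_frac, p
      ))
    }
  }
  prob <- as.numeric(predict(model$fit, newdata = as.data.frame(newdata),
                             type = "response"))
  tibble::tibble(row = newdata$row, col = newdata$col, probability = prob)
}

#' Partial response curve of a fitted predictor
#'
#' Evaluates the centred smooth effect of one predictor on the logit
#' scale over a grid of values, with pointwise 95% confidence bands from
#' the coefficient covariance (effect +/- 1.96 standard errors). The
#' `probability` columns translate the curve to the probability scale by
#' adding the model intercept, i.e. the occurrence probability with the
#' remaining predictors held at their (centred) training reference.
#'
#' @param model An `eelgrass_sdm`.
#' @param predictor Name of the predictor.
#' @param values Evaluation grid; defaults to 200 points spanning the
#'   training range.
#' @param level Confidence level for the bands.
#' @return A `response_curve` tibble with columns `predictor`, `value`,
#'   `effect`, `lower`, `upper` (logit scale) and `probability`,
#'   `probability_lower`, `probability_upper`.
#' @export
response_curve <- function(model, predictor, values = NULL, level = 0.95) {
  if (!predictor %in% model$predictors) {
    abort(paste0("Unknown predictor `", predictor, "`."))
  }
  if (is.null(values)) {
    rng <- model$training_ranges[[predictor]]
    values <- seq(rng[1], rng[2], length.out = 200)
  }
  newdata <- purrr::map(
    rlang::set_names(model$predictors),
    ~ rep(mean(model$training_ranges[[.x]]), length(values))
  )
  newdata[[predictor]] <- values
  pred <- predict(model$fit, newdata = as.data.frame(newdata),
                  type = "terms", se.fit = TRUE)
  term <- grep(paste0("s\\(", predictor, "\\)"), colnames(pred$fit))
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect <- unname(pred$fit[, term])
  se <- unname(pred$se.fit[, term])
  intercept <- unname(stats::coef(model$fit)[1])
  structure(
    tibble::tibble(
      predictor = predictor, value = values,
      effect = effect, lower = effect - z * se, upper = effect + z * se,
      probability = plogis(intercept + effect),
      probability_lower = plogis(intercept + effect - z * se),
      probability_upper = plogis(intercept + effect + z * se)
    ),
    class = c("response_curve", class(tibble::tibble()))
  )
}

#' Predictor value at which a response curve crosses a probability
#'
#' Linear interpolation of the first crossing of `probability` through
#' `p`, scanning along increasing predictor values. Returns `NA` when the
#' curve never crosses.
#'
#' @param curve A `response_curve`.
#' @param p Target probability (default 0.5).
#' @return The interpolated predictor value, or `NA`.
#' @export
curve_crossing <- function(curve, p = 0.5) {
  prob <- curve$probability
  x <- curve$value
  s <- sign(prob - p)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (length(idx) == 0) {
    if (any(s == 0)) return(x[which(s == 0)[1]])
    return(NA_real_)
  }
  i <- idx[1]
  x[i] + (p - prob[i]) * (x[i + 1] - x[i]) / (prob[i + 1] - prob[i])
}

#' Predictor contributions by drop-one deviance loss
#'
#' Refits the model with each predictor dropped in turn; the contribution
#' of a predictor is the explained deviance lost when it is dropped,
#' normalized across predictors to sum to 100%.
#'
#' @param model An `eelgrass_sdm` (its stored training sample is reused
#'   for the refits, or pass `sample` to override).
#' @param sample Optional replacement training sample.
#' @return A tibble `predictor`, `deviance_loss`, `contribution` (%).
#' @export
predictor_contributions <- function(model, sample = model$data) {
  if (length(model$predictors) < 2) {
    abort("Contributions need at least two predictors.")
  }
  d_full <- model$fit$null.deviance - model$fit$deviance
  losses <- purrr::map_dbl(
    rlang::set_names(model$predictors),
    function(drop) {
      reduced <- fit_occurrence_gam(
        sample, predictors = setdiff(model$predictors, drop), df = model$df
      )
      d_red <- reduced$fit$null.deviance - reduced$fit$deviance
      d_full - d_red
    }
  )
  tibble::tibble(
    predictor = names(losses),
    deviance_loss = unname(losses),
    contribution = 100 * unname(losses) / sum(losses)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' presence is scored above a randomly chosen absence, with ties counted
#' half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)) # 1
#' roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)) # 0.75
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Verbal discrimination class of an AUC value
#'
#' Standard interpretation bands: 0.5 no discrimination, below 0.7 low,
#' 0.7 to 0.8 acceptable, 0.8 to 0.9 excellent, above 0.9 outstanding.
#'
#' @param auc AUC value(s) in `[0.5, 1]` (vectorised).
#' @return Character vector of class labels.
#' @examples
#' auc_discrimination(0.77) # "acceptable"
#' @export
auc_discrimination <- function(auc) {
  dplyr::case_when(
    auc <= 0.5 ~ "none",
    auc < 0.7 ~ "low",
    auc < 0.8 ~ "acceptable",
    auc <= 0.9 ~ "excellent",
    TRUE ~ "outstanding"
  )
}

#' Five-fold cross-validated AUC
#'
#' Stratified k-fold resampling: records of each class are dealt to folds
#' at random, each fold is withheld in turn while the model is refitted
#' on the remainder, and the withheld fold is scored by AUC.
#'
#' @param sample A `balanced_sample` (or compatible tibble).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @inheritParams fit_occurrence_gam
#' @return An `eelgrass_cv` object wrapping a tibble of per-fold AUCs;
#'   [glance()] returns mean and SD.
#' @export
crossvalidate_auc <- function(sample, k = 5, seed = 1L,
                              predictors = c("pfd", "mov"), df = 4) {
  folds <- with_seed(seed, {
    f <- integer(nrow(sample))
    for (cls in unique(sample$presence)) {
      idx <- which(sample$presence == cls)
      f[idx] <- base::sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  per_fold <- purrr::map_dbl(seq_len(k), function(i) {
    train <- sample[folds != i, , drop = FALSE]
    test <- sample[folds == i, , drop = FALSE]
    if (length(unique(test$presence)) < 2 ||
        length(unique(train$presence)) < 2) {
      abort("A fold lost one of the classes; use fewer folds.")
    }
    m <- fit_occurrence_gam(train, predictors = predictors, df = df)
    scores <- predict(m$fit, newdata = as.data.frame(test),
                      type = "response")
    roc_auc(as.numeric(scores), test$presence)
  })
  structure(
    list(
      folds = tibble::tibble(fold = seq_len(k), auc = per_fold),
      k = k, seed = seed, n = nrow(sample)
    ),
    class = "eelgrass_cv"
  )
}

#' @export
print.eelgrass_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validated AUC: %.3f +/- %.3f (%s discrimination)\n",
    x$k, mean(x$folds$auc), sd(x$folds$auc),
    auc_discrimination(mean(x$folds$auc))
  ))
  invisible(x)
}

#' @rdname fit_occurrence_gam
#' @param x An `eelgrass_sdm`.
#' @param ... Unused.
#' @method tidy eelgrass_sdm
#' @export
tidy.eelgrass_sdm <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    term = rownames(s$s.table),
    edf = s$s.table[, "edf"],
    statistic = s$s.table[, "Chi.sq"],
    p.value = s$s.table[, "p-value"]
  )
}

#' @rdname fit_occurrence_gam
#' @method glance eelgrass_sdm
#' @export
glance.eelgrass_sdm <- function(x, ...) {
  train_auc <- roc_auc(as.numeric(x$fit$fitted.values), x$data$presence)
  tibble::tibble(
    n = x$n,
    prevalence = x$prevalence,
    deviance = x$fit$deviance,
    null.deviance = x$fit$null.deviance,
    explained.deviance = explained_deviance(x),
    auc.training = train_auc
  )
}

#' @rdname crossvalidate_auc
#' @param x An `eelgrass_cv`.
#' @param ... Unused.
#' @method tidy eelgrass_cv
#' @export
tidy.eelgrass_cv <- function(x, ...) x$folds

#' @rdname crossvalidate_auc
#' @method glance eelgrass_cv
#' @export
glance.eelgrass_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n,
    auc.mean = mean(x$folds$auc), auc.sd = sd(x$folds$auc),
    discrimination = auc_discrimination(mean(x$folds$auc))
  )
}
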