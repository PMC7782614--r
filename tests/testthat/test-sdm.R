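separable_sample <- function(n = 300, seed = 1) {
  withr::with_seed(seed, {
    # margin around the separating threshold keeps held-out points
    # unambiguous in cross-validation refits
    mov <- c(runif(ceiling(n / 2), 0, 0.35), runif(floor(n / 2), 0.45, 1))
    tibble::tibble(
      presence = as.integer(mov < 0.4),
      pfd = runif(n, 10, 500),
      mov = mov
    )
  })
}

test_that("prevalence balancing subsamples the majority class exactly", {
  obs <- tibble::tibble(
    presence = rep(c(1L, 0L), c(100, 300)),
    pfd = seq_len(400), mov = rev(seq_len(400))
  )
  bal <- balance_prevalence(obs, seed = 1)
  expect_equal(sum(bal$presence == 1), 100)
  expect_equal(sum(bal$presence == 0), 100)
  expect_equal(attr(bal, "prevalence"), 0.5)
  # balanced input passes through unchanged
  even <- obs[51:150, ]
  expect_equal(nrow(balance_prevalence(even, seed = 1)), 100)
  # determinism
  expect_identical(balance_prevalence(obs, seed = 3),
                   balance_prevalence(obs, seed = 3))
  expect_error(balance_prevalence(obs[1:100, ]), "Both")
})

test_that("a separable sample is fitted to perfect training discrimination", {
  sample <- separable_sample()
  m <- suppressWarnings(fit_occurrence_gam(sample))
  expect_equal(roc_auc(as.numeric(m$fit$fitted.values), sample$presence), 1)
})

test_that("labels independent of the predictors give a near-null fit", {
  sample <- withr::with_seed(11, tibble::tibble(
    presence = rbinom(2000, 1, 0.5),
    pfd = runif(2000, 10, 500),
    mov = runif(2000, 0, 1)
  ))
  m <- fit_occurrence_gam(sample)
  expect_lt(1 - m$fit$deviance / m$fit$null.deviance, 0.02)
})

test_that("degenerate training inputs are rejected", {
  sample <- separable_sample(60)
  expect_error(fit_occurrence_gam(sample[1:8, ]), "Too few")
  const <- dplyr::mutate(separable_sample(200), pfd = 1)
  expect_error(fit_occurrence_gam(const), "constant")
  inf <- dplyr::mutate(separable_sample(200),
                       pfd = replace(pfd, 1, Inf))
  expect_error(fit_occurrence_gam(inf), "Non-finite")
})

test_that("mean fitted probability equals the training prevalence", {
  world <- small_world()
  pfd <- pfd_predictor_field(world$forcing$secchi$BAU, world$grid, 2007:2011)
  mov <- mov_predictor_field(world$forcing$waves$A1B_1, world$grid,
                             2007:2011)
  obs <- sample_observations(world$grid, pfd, mov, n = 500, seed = 2)
  bal <- balance_prevalence(obs, seed = 3)
  m <- fit_occurrence_gam(bal)
  expect_lt(abs(mean(m$fit$fitted.values) - m$prevalence), 0.02)
  pred <- predict_probability(m, pfd, mov)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_equal(nrow(pred), sum(world$grid$in_scope))
})

test_that("prediction is a pointwise function of the predictor pair", {
  sample <- separable_sample(400)
  m <- suppressWarnings(fit_occurrence_gam(sample))
  one <- tibble::tibble(row = 1:5, col = 1L,
                        pfd = sample$pfd[7], mov = sample$mov[7])
  pred <- predict_probability(m, one[c("row", "col", "pfd")],
                              one[c("row", "col", "mov")])
  expect_equal(unique(round(pred$probability, 10)),
               round(as.numeric(m$fit$fitted.values[7]), 10))
})

test_that("extrapolation beyond the training range warns but proceeds", {
  sample <- separable_sample(400)
  m <- suppressWarnings(fit_occurrence_gam(sample))
  far <- tibble::tibble(row = 1L, col = 1L, pfd = 5000, mov = 0.2)
  expect_warning(
    predict_probability(m, far[c("row", "col", "pfd")],
                        far[c("row", "col", "mov")]),
    "extrapolate"
  )
})

test_that("response curves carry bands that bracket the central curve", {
  world <- small_world()
  pfd <- pfd_predictor_field(world$forcing$secchi$BAU, world$grid, 2007:2011)
  mov <- mov_predictor_field(world$forcing$waves$A1B_1, world$grid,
                             2007:2011)
  obs <- sample_observations(world$grid, pfd, mov, n = 500, seed = 4)
  m <- fit_occurrence_gam(balance_prevalence(obs, seed = 5))
  for (p in c("pfd", "mov")) {
    rc <- response_curve(m, p)
    expect_true(all(rc$lower <= rc$effect & rc$effect <= rc$upper))
    expect_true(all(rc$probability_lower <= rc$probability &
                      rc$probability <= rc$probability_upper))
  }
  # centred smooth: effect crosses zero inside the data range
  rc <- response_curve(m, "mov")
  expect_lt(min(abs(rc$effect)), 0.5)
  # bands widen at the data-sparse extremes relative to the centre
  width <- rc$upper - rc$lower
  expect_gt(max(width[c(1, length(width))]),
            width[which.min(abs(rc$value - stats::median(m$data$mov)))])
  expect_error(response_curve(m, "salinity"), "Unknown")
})

test_that("rank-based AUC agrees with brute force over all pairs", {
  brute_auc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    grid <- expand.grid(p = pos, n = neg)
    mean((grid$p > grid$n) + 0.5 * (grid$p == grid$n))
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(4:40, 1)
      scores <- round(runif(n), 2) # coarse scores force ties
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
    }
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), "Both classes")
})

test_that("rank-based AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    scores <- runif(500)
    labels <- rbinom(500, 1, plogis(3 * scores - 1.5))
    expect_equal(
      roc_auc(scores, labels),
      as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
    )
  })
})

test_that("AUC interpretation bands follow the standard labels", {
  expect_equal(auc_discrimination(c(0.5, 0.65, 0.7, 0.77, 0.85, 0.95)),
               c("none", "low", "acceptable", "acceptable", "excellent",
                 "outstanding"))
})

test_that("cross-validation is stratified, deterministic and calibrated", {
  sample <- separable_sample(400)
  cv <- suppressWarnings(crossvalidate_auc(sample, seed = 1))
  expect_equal(cv$folds$auc, rep(1, 5))
  expect_identical(
    suppressWarnings(crossvalidate_auc(sample, seed = 2))$folds,
    suppressWarnings(crossvalidate_auc(sample, seed = 2))$folds
  )
  g <- glance(cv)
  expect_true(g$auc.mean >= min(cv$folds$auc) &
                g$auc.mean <= max(cv$folds$auc))
})

test_that("label-permuted data cross-validates to chance AUC", {
  sample <- withr::with_seed(23, tibble::tibble(
    presence = rbinom(2000, 1, 0.5),
    pfd = runif(2000, 10, 500),
    mov = runif(2000, 0, 1)
  ))
  cv <- crossvalidate_auc(sample, seed = 3)
  expect_lt(abs(mean(cv$folds$auc) - 0.5), 0.05)
})

test_that("drop-one contributions are normalized and detect information", {
  # one informative predictor, one pure noise
  sample <- withr::with_seed(31, {
    mov <- runif(1500, 0, 1)
    tibble::tibble(
      presence = rbinom(1500, 1, plogis(-6 * (mov - 0.4))),
      pfd = runif(1500, 10, 500),
      mov = mov
    )
  })
  m <- fit_occurrence_gam(sample)
  contrib <- predictor_contributions(m)
  expect_equal(sum(contrib$contribution), 100)
  expect_gt(contrib$contribution[contrib$predictor == "mov"], 90)
})

test_that("exchangeable predictor copies split the contribution evenly", {
  sample <- withr::with_seed(37, {
    x1 <- runif(4000, -2, 2)
    x2 <- runif(4000, -2, 2)
    tibble::tibble(
      presence = rbinom(4000, 1, plogis(x1 + x2)),
      pfd = x1, mov = x2
    )
  })
  m <- fit_occurrence_gam(sample)
  contrib <- predictor_contributions(m)
  expect_equal(contrib$contribution, c(50, 50), tolerance = 0.1)
})

test_that("tidy and glance expose the fit in broom conventions", {
  sample <- separable_sample(300)
  m <- suppressWarnings(fit_occurrence_gam(sample))
  td <- tidy(m)
  expect_equal(td$term, c("s(pfd)", "s(mov)"))
  expect_equal(unname(td$edf), c(4, 4), tolerance = 1e-6)
  g <- glance(m)
  expect_equal(g$n, 300)
  expect_equal(g$auc.training, 1)
})
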