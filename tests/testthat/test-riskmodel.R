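test_that("EPV rule caps the predictor count", {
  expect_equal(epv_max_predictors(20), 4L)
  expect_equal(epv_max_predictors(19), 3L)
  expect_equal(epv_max_predictors(5), 1L)
})

test_that("logistic fit recovers known coefficients and matches glm", {
  dat <- withr::with_seed(9, {
    X <- matrix(rnorm(4000), ncol = 2)
    y <- rbinom(2000, 1, plogis(0.3 + X %*% c(1.5, -0.7)))
    list(X = X, y = y)
  })
  fit <- fit_logistic(dat$X, dat$y)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[1] - 1.5), 0.15)
  expect_lt(abs(fit$coefficients[2] + 0.7), 0.15)
  ref <- glm(dat$y ~ dat$X, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
})

test_that("null model yields class-balance intercept; misuse errors are clear", {
  y <- c(rep(1, 20), rep(0, 33))
  fit <- fit_logistic(matrix(1, 53, 1), y, regularization = 1e-4)
  expect_lt(abs(fit$intercept + sum(fit$coefficients) - qlogis(20 / 53)), 1e-4)
  expect_error(fit_logistic(matrix(1, 53, 1), y), "zero-variance")
  expect_error(fit_logistic(matrix(rnorm(10)), rep(1, 10)), "single class")
})

test_that("separation triggers the ridge refit path and stays predictive", {
  x <- matrix(c(1:10), ncol = 1)
  y <- c(rep(0, 5), rep(1, 5))
  expect_warning(fit <- fit_logistic(x, y), "separation")
  expect_true(fit$separation_refit)
  expect_true(fit$converged)
  expect_equal(fit$regularization, 1e-4)
  expect_true(all((predict(fit, x) > 0.5) == (y == 1)))
})

test_that("AUC matches exhaustive pair counting, handles ties, and is rank invariant", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  for (seed in 1:6) {
    d <- withr::with_seed(seed, {
      list(s = sample(seq(0, 1, 0.1), 12, TRUE), y = rbinom(12, 1, 0.5))
    })
    if (length(unique(d$y)) < 2) next
    expect_equal(auc(d$s, d$y), oracle_auc(d$s, d$y))
    # invariance under a strictly monotone transform
    expect_equal(auc(exp(3 * d$s), d$y), auc(d$s, d$y))
  }
  expect_error(auc(1:3, c(1, 1, 1)), "single class")
})

test_that("LOOCV metrics reconstruct the confusion table and honor edge cases", {
  dat <- withr::with_seed(21, {
    X <- matrix(rnorm(60), ncol = 1)
    y <- rbinom(60, 1, plogis(2 * X))
    list(X = X, y = y)
  })
  rep <- loocv(dat$X, dat$y)
  P <- sum(dat$y); N <- length(dat$y)
  expect_equal(rep$accuracy * N, rep$sensitivity * P + rep$specificity * (N - P),
               tolerance = 1e-12)
  expect_length(rep$oof_probabilities, N)

  # perfectly separable predictor: perfect out-of-fold prediction
  sep <- suppressWarnings(loocv(matrix(c(1:10, 31:40), ncol = 1),
                                c(rep(0, 10), rep(1, 10))))
  expect_equal(sep$accuracy, 1)
  expect_equal(sep$auc_testing, 1)

  # constant predictor: every fold predicts the training class rate
  con <- loocv(matrix(1, 53, 1), c(rep(1, 20), rep(0, 33)), regularization = 1e-4)
  expect_equal(con$accuracy, 33 / 53)
  expect_equal(con$sensitivity, 0)
  expect_equal(con$specificity, 1)

  # duplicated predictor columns leave the ridge report unchanged
  X2 <- cbind(dat$X, dat$X)
  r1 <- loocv(dat$X, dat$y, regularization = 1e-4)
  r2 <- loocv(X2, dat$y, regularization = 1e-4)
  expect_equal(r1$oof_probabilities, r2$oof_probabilities, tolerance = 1e-4)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("predictor-set evaluation enforces the EPV cap and is order invariant", {
  atlas <- toy_atlas(24, 3, 3, seed = 6)
  truth <- ground_truth(atlas$region_id[atlas$planted_role == "hub"],
                        atlas$region_id[atlas$planted_role == "lateral_high_strain"],
                        1.8, 0.83)
  im <- gen_impacts(atlas, 53, 20, truth, seed = 6)
  rk <- rank_by_strain(im)
  expect_error(evaluate_predictor_sets(im, rk, max_k = 5), "events-per-variable")

  ev <- suppressWarnings(evaluate_predictor_sets(im, rk, max_k = 4))
  expect_equal(nrow(ev), 9)  # 4 kinematics + MPS95 + top-1..4
  expect_true(all(ev$accuracy >= 0 & ev$accuracy <= 1))

  # permuting the order of a shared top-k set leaves the report unchanged
  rk2 <- rk
  top4 <- order(rk$rank)[1:4]
  rk2$rank[top4] <- rk$rank[top4][c(3, 1, 4, 2)]
  ev2 <- suppressWarnings(evaluate_predictor_sets(im, rk2, max_k = 4,
                                                  include_univariate = FALSE))
  expect_equal(ev$accuracy[ev$predictor_set == "strain_rank_top4"],
               ev2$accuracy[ev2$predictor_set == "strain_rank_top4"])
  expect_equal(ev$auc_testing[ev$predictor_set == "strain_rank_top4"],
               ev2$auc_testing[ev2$predictor_set == "strain_rank_top4"])

  # an informative top region beats the majority-class rate on effect data
  expect_gt(ev$accuracy[ev$predictor_set == "strain_rank_top1"], 33 / 53)
})

test_that("per-subject evaluation reports ordered spread and zero-noise degeneracy", {
  atlas <- toy_atlas(24, 3, 3, seed = 8)
  truth <- ground_truth(atlas$region_id[atlas$planted_role == "hub"],
                        atlas$region_id[atlas$planted_role == "lateral_high_strain"],
                        1.8, 0.83)
  im <- gen_impacts(atlas, 40, 15, truth, seed = 8)

  cohort0 <- gen_cohort(atlas, n_subjects = 3, between_subject_noise = 0, seed = 8,
                        density = 0.3)
  ranks0 <- lapply(lapply(cohort0, lesion_sweep, k = 1), aggregate_importance)
  res0 <- per_subject_evaluation(im, ranks0, k = 3)
  expect_equal(res0$summary$accuracy[["min"]], res0$summary$accuracy[["max"]])

  cohort <- gen_cohort(atlas, n_subjects = 4, between_subject_noise = 0.5, seed = 8,
                       density = 0.3)
  ranks <- lapply(lapply(cohort, lesion_sweep, k = 1), aggregate_importance)
  res <- per_subject_evaluation(im, ranks, k = 3)
  s <- res$summary$accuracy
  expect_lte(s[["min"]], s[["mean"]])
  expect_lte(s[["mean"]], s[["max"]])
  expect_equal(nrow(res$per_subject), 4)
  expect_error(per_subject_evaluation(im, ranks, k = 4), "events-per-variable")
})
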