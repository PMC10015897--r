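# build a shap_explanation by hand (the fit operates on the object contract)
mock_explanation <- function(L, phi, feature = "conju_max_distance") {
  v <- matrix(phi, ncol = 1, dimnames = list(NULL, feature))
  fv <- matrix(L, ncol = 1, dimnames = list(NULL, feature))
  structure(list(values = v, base_value = 0, feature_values = fv,
                 prediction = phi), class = "shap_explanation")
}

test_that("a noiseless lg-linear profile is recovered exactly", {
  L <- rep(c(3, 5, 9, 15, 21), each = 4)
  phi <- 1.8 * log10(L) - 2
  fit <- fit_power_law(mock_explanation(L, phi))
  expect_equal(fit$exponent, 1.8, tolerance = 1e-10)
  expect_equal(fit$intercept, -2, tolerance = 1e-10)
  expect_equal(fit$stderr, 0, tolerance = 1e-8)
})

test_that("degenerate profiles are rejected", {
  expect_error(fit_power_law(mock_explanation(rep(c(3, 5), 5), rnorm(10))),
               "degenerate")
  expect_error(fit_power_law(mock_explanation(c(0, 3, 5, 9), rnorm(4))),
               "positive")
  expect_error(fit_power_law(mock_explanation(1:5, rnorm(5)), feature = "zz"),
               "not in explanation")
})

test_that("the OLS interval covers a planted exponent at the expected rate", {
  covered <- vapply(1:20, function(s) {
    set.seed(s)
    L <- sample(c(3, 5, 7, 9, 11, 15, 19, 27), 400, replace = TRUE)
    phi <- 1.8 * log10(L) - 2 + rnorm(400, 0, 0.1)
    fit <- fit_power_law(mock_explanation(L, phi))
    abs(fit$exponent - 1.8) <= 2 * fit$stderr
  }, TRUE)
  expect_gte(sum(covered), 17)
})

test_that("add-one-feature refit splits attribution between duplicated columns", {
  set.seed(31)
  x <- matrix(rnorm(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * x[, 1] + x[, 2] + rnorm(300, 0, 0.2)
  hyper <- list(xgb = list(nrounds = 150, max_depth = 4))
  spec <- tpa_regressors(hyper)$xgb
  base_model <- spec$fit(x, y, seed = 31, h = spec$hyperparameters)
  base_ex <- shap_values(base_model, x)
  twin <- matrix(x[, "a"], ncol = 1, dimnames = list(NULL, "a_twin"))
  ex <- add_feature_and_refit(x, twin, y, seed = 31, hyper = hyper)
  expect_equal(attr(ex, "extra_feature"), "a_twin")
  shared <- ex$values[, "a"] + ex$values[, "a_twin"]
  expect_gt(cor(shared, base_ex$values[, "a"]), 0.95)
  expect_lt(mean(abs(shared - base_ex$values[, "a"])), 0.1)
  expect_error(add_feature_and_refit(x, matrix(1:300, ncol = 1,
                                               dimnames = list(NULL, "a")), y),
               "already in matrix")
})

test_that("noise features earn small attributions and causal ones large", {
  set.seed(32)
  x <- matrix(rnorm(400 * 2), 400, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1.5 * x[, 1] + 0.8 * x[, 2] + rnorm(400, 0, 0.2)
  hyper <- list(xgb = list(nrounds = 150, max_depth = 4))
  noise <- matrix(rnorm(400), ncol = 1, dimnames = list(NULL, "noise"))
  exn <- add_feature_and_refit(x, noise, y, seed = 32, hyper = hyper)
  expect_lt(mean(abs(exn$values[, "noise"])), 0.05)
  causal <- matrix(0.7 * scale(y)[, 1] + 0.3 * rnorm(400), ncol = 1,
                   dimnames = list(NULL, "causal"))
  exc <- add_feature_and_refit(x, causal, y, seed = 32, hyper = hyper)
  expect_gt(mean(abs(exc$values[, "causal"])), mean(abs(exn$values[, "noise"])))
})

test_that("ALE recovers linear effects, ignores unused features, and is centred", {
  set.seed(33)
  x <- matrix(rnorm(500 * 2), 500, 2, dimnames = list(NULL, c("u", "v")))
  lin_model <- list()
  lin_fun <- function(model, m) 2 * m[, "u"] + 1
  pr <- ale_profile(lin_model, x, "u", n_bins = 10, predict_fun = lin_fun)
  expect_equal(ale_slope(pr), 2, tolerance = 0.1)
  expect_lt(abs(sum(pr$bin_counts * pr$cumulative) / sum(pr$bin_counts)), 1e-9)
  prv <- ale_profile(lin_model, x, "v", n_bins = 10, predict_fun = lin_fun)
  expect_lt(max(abs(prv$cumulative)), 1e-9)
  expect_error(ale_profile(lin_model, cbind(x, w = rep(1, 500)), "w",
                           predict_fun = lin_fun), "constant")
})

test_that("ALE and SHAP slopes agree on an additive boosted model", {
  set.seed(34)
  x <- matrix(rnorm(500 * 2), 500, 2, dimnames = list(NULL, c("u", "v")))
  y <- 1.5 * x[, "u"] - x[, "v"] + rnorm(500, 0, 0.2)
  spec <- tpa_regressors(list(xgb = list(nrounds = 300)))$xgb
  m <- spec$fit(x, y, seed = 34, h = spec$hyperparameters)
  ex <- shap_values(m, x)
  shap_slope <- unname(coef(lm(ex$values[, "u"] ~ x[, "u"]))[2])
  pr <- ale_profile(m, x, "u", n_bins = 20)
  expect_lt(abs(ale_slope(pr) - shap_slope) / abs(shap_slope), 0.1)
})
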