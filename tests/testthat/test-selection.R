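light_hyper <- list(xgb = list(nrounds = 120, max_depth = 4),
                    gbrt = list(nrounds = 80, max_depth = 3))

test_that("importance vectors are normalized and reproducible", {
  fx <- make_regression_fixture(150, 2, 4, coefficients = c(2, 1),
                                sigma = 0.3, seed = 1)
  rep1 <- combined_importance(fx$x, fx$y, n_runs = 4, base_seed = 1,
                              hyper = light_hyper)
  for (m in attr(rep1, "methods_used")) {
    expect_equal(sum(rep1[[m]]), 1, tolerance = 1e-9)
  }
  expect_equal(sum(rep1$combined), 1, tolerance = 1e-9)
  rep2 <- combined_importance(fx$x, fx$y, n_runs = 4, base_seed = 1,
                              hyper = light_hyper)
  expect_identical(rep1, rep2)
})

test_that("a single informative feature dominates the combined importance", {
  hits <- vapply(1:5, function(s) {
    fx <- make_regression_fixture(300, 1, 9, coefficients = 3, sigma = 0.3,
                                  seed = s)
    rep_ <- combined_importance(fx$x, fx$y, n_runs = 4, base_seed = s,
                                hyper = light_hyper)
    rep_$feature[which.max(rep_$combined)] == "x1"
  }, TRUE)
  expect_equal(sum(hits), 5)
})

test_that("two symmetric informative features get comparable importance", {
  fx <- make_regression_fixture(600, 2, 2, coefficients = c(1, 1),
                                sigma = 0.2, seed = 9)
  rep_ <- combined_importance(fx$x, fx$y, n_runs = 8, base_seed = 9,
                              hyper = light_hyper)
  i1 <- rep_$combined[rep_$feature == "x1"]
  i2 <- rep_$combined[rep_$feature == "x2"]
  expect_lt(abs(i1 - i2) / max(i1, i2), 0.25)
})

test_that("importance ranking follows planted coefficient magnitudes", {
  ok <- vapply(1:3, function(s) {
    fx <- make_regression_fixture(1000, 4, 0, coefficients = c(0, 1, 2, 4),
                                  sigma = 0.3, seed = s)
    rep_ <- combined_importance(fx$x, fx$y, n_runs = 4, base_seed = s,
                                hyper = light_hyper)
    identical(order(rep_$combined), 1:4)
  }, TRUE)
  expect_gte(sum(ok), 2)
})

test_that("backward elimination removes a constant column first and stops at stop_size", {
  set.seed(4)
  x <- cbind(x1 = rnorm(120), x2 = rnorm(120), konst = rep(2, 120))
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(120, 0, 0.2)
  tr <- backward_eliminate(x, y, refresh_every = 10, stop_size = 2,
                           eval_runs = 2, importance_runs = 2, base_seed = 4,
                           hyper = light_hyper)
  expect_equal(tr$feature[tr$action == "remove"][1], "konst")
  expect_setequal(attr(tr, "selected"), c("x1", "x2"))
  expect_equal(tr$size, c(3, 2))
  expect_true(all(tr$mse_mean >= 0))
  # stop_size = width leaves nothing to remove
  tr0 <- backward_eliminate(x, y, stop_size = 3, eval_runs = 2,
                            importance_runs = 2, base_seed = 4,
                            hyper = light_hyper)
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$action, "init")
})

test_that("backward elimination retains planted features (majority of seeds)", {
  ok <- vapply(1:5, function(s) {
    fx <- make_regression_fixture(300, 2, 8, coefficients = c(1, 1),
                                  sigma = 0.3, seed = s)
    tr <- backward_eliminate(fx$x, fx$y, refresh_every = 10, stop_size = 2,
                             eval_runs = 2, importance_runs = 6, base_seed = s,
                             hyper = light_hyper)
    setequal(attr(tr, "selected"), c("x1", "x2"))
  }, TRUE)
  expect_gte(sum(ok), 4)
})

test_that("forward stepwise adds the planted partner of the seed first", {
  ok <- vapply(1:5, function(s) {
    fx <- make_regression_fixture(300, 2, 8, coefficients = c(1, 1),
                                  sigma = 0.3, seed = s)
    fw <- forward_stepwise(fx$x, fx$y, seed_features = "x1", tolerance = 0.01,
                           eval_runs = 3, base_seed = s, hyper = light_hyper,
                           max_steps = 1)
    identical(attr(fw, "selected"), c("x1", "x2"))
  }, TRUE)
  expect_gte(sum(ok), 4)
})

test_that("forward stepwise stops immediately when the seed suffices", {
  fx <- make_regression_fixture(300, 1, 5, coefficients = 2, sigma = 0.3,
                                seed = 3)
  fw <- forward_stepwise(fx$x, fx$y, seed_features = "x1", tolerance = 0.01,
                         eval_runs = 3, base_seed = 3, hyper = light_hyper)
  expect_identical(attr(fw, "selected"), "x1")
  # infinite tolerance always yields the seed-only trace
  fwinf <- forward_stepwise(fx$x, fx$y, seed_features = "x1", tolerance = Inf,
                            eval_runs = 2, base_seed = 3, hyper = light_hyper)
  expect_equal(nrow(fwinf), 1)
  # empty candidate pool returns the seed-only trace
  fw0 <- forward_stepwise(fx$x[, "x1", drop = FALSE], fx$y,
                          seed_features = "x1", eval_runs = 2, base_seed = 3,
                          hyper = light_hyper)
  expect_equal(nrow(fw0), 1)
  expect_error(forward_stepwise(fx$x, fx$y, seed_features = "missing"),
               "seed feature")
})

test_that("traces are byte-identical under the same seed", {
  fx <- make_regression_fixture(150, 2, 3, coefficients = c(1, 1),
                                sigma = 0.3, seed = 6)
  a <- backward_eliminate(fx$x, fx$y, stop_size = 2, eval_runs = 2,
                          importance_runs = 3, base_seed = 6, hyper = light_hyper)
  b <- backward_eliminate(fx$x, fx$y, stop_size = 2, eval_runs = 2,
                          importance_runs = 3, base_seed = 6, hyper = light_hyper)
  expect_identical(a, b)
})
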