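test_that("split arithmetic matches the 85:15 protocol", {
  proto <- cv_protocol(n_runs = 5, test_fraction = 0.15, base_seed = 7)
  sp <- cv_split(856, proto, 1)
  expect_length(sp$train, 728)
  expect_length(sp$test, 128)
  sp20 <- cv_split(20, proto, 1)
  expect_length(sp20$train, 17)
  expect_length(sp20$test, 3)
  # determinism, disjointness, exhaustiveness over runs
  for (r in 1:5) {
    a <- cv_split(100, proto, r)
    b <- cv_split(100, proto, r)
    expect_identical(a, b)
    expect_length(intersect(a$train, a$test), 0)
    expect_setequal(c(a$train, a$test), 1:100)
  }
  expect_false(identical(cv_split(100, proto, 1), cv_split(100, proto, 2)))
  expect_error(cv_split(4, cv_protocol(1, 0.15, 1), 1), "test fraction")
})

test_that("metric identities hold on a hand-computed example", {
  obs <- c(1, 2, 3, 4)
  pred <- c(1.5, 2, 2, 5)
  m <- tpascreen:::.metrics(obs, pred)
  expect_equal(m[["mse"]], (0.25 + 0 + 1 + 1) / 4)
  expect_equal(m[["mae"]], (0.5 + 0 + 1 + 1) / 4)
  expect_equal(m[["r2"]], 1 - 2.25 / 5)
  exact <- tpascreen:::.metrics(obs, obs)
  expect_equal(unname(exact), c(0, 0, 1))
})

test_that("evaluation metrics satisfy their invariants on synthetic data", {
  fx <- make_regression_fixture(200, 2, 2, coefficients = c(1, 0.5),
                                sigma = 0.3, seed = 2)
  ev <- evaluate(fx$x, fx$y, "gbrt", cv_protocol(6, 0.15, 3),
                 hyper = list(gbrt = list(nrounds = 80)))
  ok <- !ev$runs$failed
  expect_true(all(ev$runs$mse[ok] >= 0))
  expect_true(all(ev$runs$mae[ok] <= sqrt(ev$runs$mse[ok]) + 1e-12))
  expect_true(all(ev$runs$r2[ok] <= 1))
  expect_true(all(ev$per_sample$pred_sd >= 0, na.rm = TRUE))
})

test_that("a constant predictor scores R2 about zero", {
  const_spec <- structure(list(
    name = "const", deterministic = TRUE, hyperparameters = list(),
    fit = function(x, y, seed, h) mean(y),
    predict = function(model, x) rep(model, nrow(x))
  ), class = "regressor_spec")
  fx <- make_regression_fixture(400, 1, 1, sigma = 0.2, seed = 5)
  ev <- evaluate(fx$x, fx$y, const_spec, cv_protocol(10, 0.15, 5))
  expect_lt(abs(ev$r2), 0.1)
})

test_that("held-out MSE of a boosted model on a linear signal sits near the noise floor", {
  fx <- make_regression_fixture(500, 2, 0, coefficients = c(1, 0.5),
                                sigma = 0.3, seed = 11)
  ev <- evaluate(fx$x, fx$y, "gbrt", cv_protocol(40, 0.15, 11),
                 hyper = list(gbrt = list(nrounds = 200)))
  expect_gt(ev$mse, 0.09)  # cannot beat the noise variance
  expect_lt(ev$mse, 0.15)
})

test_that("failed runs are excluded with a warning", {
  flaky <- structure(list(
    name = "flaky", deterministic = TRUE, hyperparameters = list(),
    fit = function(x, y, seed, h) if (seed %% 2 == 0) stop("boom") else mean(y),
    predict = function(model, x) rep(model, nrow(x))
  ), class = "regressor_spec")
  fx <- make_regression_fixture(60, 1, 0, sigma = 0.1, seed = 1)
  expect_warning(ev <- evaluate(fx$x, fx$y, flaky, cv_protocol(6, 0.2, 0)),
                 "failed")
  expect_equal(sum(ev$runs$failed), 3)
  expect_false(is.na(ev$mse))
})

test_that("registry stubs refuse to fit and unknown names are rejected", {
  expect_error(evaluate(matrix(rnorm(40), 20), rnorm(20), "knn",
                        cv_protocol(1, 0.2, 1)), "stub")
  expect_error(evaluate(matrix(rnorm(40), 20), rnorm(20), "nope",
                        cv_protocol(1, 0.2, 1)), "unknown regressor")
  reg <- tpa_regressors(list(xgb = list(nrounds = 42)))
  expect_equal(reg$xgb$hyperparameters$nrounds, 42)
  expect_equal(reg$xgb$hyperparameters$max_depth, 6)
})

test_that("ensembles reproduce fitted values and respond deterministically", {
  fx <- make_regression_fixture(80, 1, 1, sigma = 0, seed = 4)
  ens <- train_ensemble(fx$x, fx$y, "rf", cv_protocol(1, 0.15, 4),
                        hyper = list(rf = list(ntree = 100)))
  sp <- cv_split(80, ens$protocol, 1)
  pr <- predict(ens, fx$x[sp$train, , drop = FALSE])
  expect_equal(pr$lg_tpacs_mean,
               as.numeric(predict(ens$models[[1]],
                                  fx$x[sp$train, , drop = FALSE])))
  expect_true(all(pr$lg_tpacs_sd >= 0))
  # duplicated inputs give identical outputs
  dup <- fx$x[c(1, 1), , drop = FALSE]
  pd <- predict(ens, dup)
  expect_equal(pd[1, ], pd[2, ], ignore_attr = TRUE)
  expect_equal(pd$tpacs_gm, 10^pd$lg_tpacs_mean)
  # feature mismatch is caught before prediction
  bad <- fx$x[1:2, , drop = FALSE]
  colnames(bad) <- c("a", "b")
  expect_error(predict(ens, bad), "lacks training features")
})
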