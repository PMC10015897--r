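# Repeated random-split cross-validation in lg(TPACS) units.
#
# The protocol mirrors the evaluation design of the modelling study this
# package implements: many random 85:15 train/test splits, with MSE, MAE and
# R^2 on the held-out sets and per-sample prediction dispersion across runs.

#' Cross-validation protocol
#'
#' @param n_runs number of random splits (study-scale default 240).
#' @param test_fraction held-out fraction (default 0.15).
#' @param base_seed integer; run `i` is seeded with `base_seed + i`.
#' @return a `cv_protocol` list.
#' @export
cv_protocol <- function(n_runs = 240, test_fraction = 0.15, base_seed = 1L) {
  stopifnot(n_runs >= 1, test_fraction > 0, test_fraction < 1)
  structure(list(n_runs = as.integer(n_runs), test_fraction = test_fraction,
                 base_seed = as.integer(base_seed)), class = "cv_protocol")
}

#' Train/test split for one CV run
#'
#' Train size is `round(n * (1 - test_fraction))`; the test set is the
#' complement (856 samples at 0.15 give 728/128).
#'
#' @param n number of samples.
#' @param protocol a `cv_protocol`.
#' @param run_index run number (1-based).
#' @return list with integer `train` and `test` index vectors.
#' @export
cv_split <- function(n, protocol, run_index) {
  stopifnot(n >= 2)
  if (n * protocol$test_fraction < 1) {
    stop("test fraction leaves no test samples for n = ", n, call. = FALSE)
  }
  n_train <- round(n * (1 - protocol$test_fraction))
  set.seed(protocol$base_seed + as.integer(run_index))
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

# ---- regressor registry ----------------------------------------------------

.xgb_fit <- function(x, y, seed, nrounds, params) {
  set.seed(seed)
  xgboost::xgb.train(
    params = c(params, list(nthread = 1, seed = seed)),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
}

#' Regressor registry
#'
#' Pluggable regressor specifications. Implemented entries carry `fit` and
#' `predict` closures; the remaining entries of the study's ten-regressor
#' panel (DNN, MLP, kNN, AdaBoost) are registered as stubs with documented
#' hyperparameter slots so external engines can be plugged in.
#'
#' @param hyper optional named list of per-regressor hyperparameter
#'   overrides, e.g. `list(xgb = list(nrounds = 300))`.
#' @return named list of `regressor_spec` entries.
#' @export
tpa_regressors <- function(hyper = list()) {
  hp <- function(name, defaults) utils::modifyList(defaults, hyper[[name]] %||% list())
  specs <- list(
    lasso = list(
      name = "lasso", deterministic = TRUE,
      hyperparameters = hp("lasso", list(nfolds = 5)),
      fit = function(x, y, seed, h) {
        set.seed(seed)
        glmnet::cv.glmnet(x, y, alpha = 1, nfolds = h$nfolds)
      },
      predict = function(model, x) as.numeric(stats::predict(model, x, s = "lambda.min")),
      importance = function(model) {
        cf <- as.numeric(stats::coef(model, s = "lambda.min"))[-1]
        abs(cf)
      }
    ),
    elasticnet = list(
      name = "elasticnet", deterministic = TRUE,
      hyperparameters = hp("elasticnet", list(nfolds = 5, alpha = 0.5)),
      fit = function(x, y, seed, h) {
        set.seed(seed)
        glmnet::cv.glmnet(x, y, alpha = h$alpha, nfolds = h$nfolds)
      },
      predict = function(model, x) as.numeric(stats::predict(model, x, s = "lambda.min")),
      importance = function(model) abs(as.numeric(stats::coef(model, s = "lambda.min"))[-1])
    ),
    gbrt = list(
      name = "gbrt", deterministic = TRUE,
      hyperparameters = hp("gbrt", list(
        nrounds = 300, max_depth = 3, eta = 0.1, subsample = 1,
        colsample_bytree = 1, min_child_weight = 1)),
      fit = function(x, y, seed, h) {
        .xgb_fit(x, y, seed, h$nrounds,
                 list(max_depth = h$max_depth, eta = h$eta,
                      subsample = h$subsample, colsample_bytree = h$colsample_bytree,
                      min_child_weight = h$min_child_weight,
                      base_score = mean(y), tree_method = "exact"))
      },
      predict = function(model, x) stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1)),
      shap = TRUE
    ),
    xgb = list(
      name = "xgb", deterministic = TRUE,
      hyperparameters = hp("xgb", list(
        nrounds = 500, max_depth = 6, eta = 0.05, subsample = 1,
        colsample_bytree = 1, min_child_weight = 2, lambda = 1)),
      fit = function(x, y, seed, h) {
        .xgb_fit(x, y, seed, h$nrounds,
                 list(max_depth = h$max_depth, eta = h$eta,
                      subsample = h$subsample, colsample_bytree = h$colsample_bytree,
                      min_child_weight = h$min_child_weight, lambda = h$lambda,
                      base_score = mean(y), tree_method = "hist"))
      },
      predict = function(model, x) stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1)),
      shap = TRUE
    ),
    rf = list(
      name = "rf", deterministic = TRUE,
      hyperparameters = hp("rf", list(ntree = 300)),
      fit = function(x, y, seed, h) {
        set.seed(seed)
        randomForest::randomForest(x, y, ntree = h$ntree)
      },
      predict = function(model, x) as.numeric(stats::predict(model, x))
    ),
    dnn = list(name = "dnn", deterministic = FALSE,
               hyperparameters = hp("dnn", list(hidden = c(64, 64), epochs = 200)),
               fit = NULL, predict = NULL),
    mlp = list(name = "mlp", deterministic = FALSE,
               hyperparameters = hp("mlp", list(hidden = 100, max_iter = 500)),
               fit = NULL, predict = NULL),
    knn = list(name = "knn", deterministic = TRUE,
               hyperparameters = hp("knn", list(k = 5)),
               fit = NULL, predict = NULL),
    adaboost = list(name = "adaboost", deterministic = TRUE,
                    hyperparameters = hp("adaboost", list(n_estimators = 100)),
                    fit = NULL, predict = NULL)
  )
  lapply(specs, function(s) structure(s, class = "regressor_spec"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_regressor <- function(regressor, hyper = list()) {
  if (inherits(regressor, "regressor_spec")) return(regressor)
  reg <- tpa_regressors(hyper)
  if (!regressor %in% names(reg)) {
    stop("unknown regressor '", regressor, "'; registered: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  spec <- reg[[regressor]]
  if (is.null(spec$fit)) {
    stop("regressor '", regressor, "' is a registry stub without a fitting engine",
         call. = FALSE)
  }
  spec
}

# ---- evaluation ------------------------------------------------------------

.metrics <- function(obs, pred) {
  e <- obs - pred
  sst <- sum((obs - mean(obs))^2)
  c(mse = mean(e^2), mae = mean(abs(e)),
    r2 = if (sst > 0) 1 - sum(e^2) / sst else NA_real_)
}

#' Repeated-CV evaluation of one regressor
#'
#' @param x numeric feature matrix (or `feature_matrix`).
#' @param y numeric targets in lg(TPACS) units.
#' @param regressor registry name or a `regressor_spec`.
#' @param protocol a `cv_protocol`.
#' @param hyper hyperparameter overrides passed to the registry.
#' @return an `eval_result`: per-run metrics, their means, and per-sample
#'   held-out prediction mean/sd across runs. Failed runs are excluded from
#'   the means with a warning.
#' @export
evaluate <- function(x, y, regressor = "xgb", protocol = cv_protocol(),
                     hyper = list()) {
  if (inherits(x, "feature_matrix")) x <- x$x
  spec <- .resolve_regressor(regressor, hyper)
  n <- nrow(x)
  runs <- data.frame(run = seq_len(protocol$n_runs), mse = NA_real_,
                     mae = NA_real_, r2 = NA_real_, failed = FALSE)
  pred_sum <- numeric(n); pred_sq <- numeric(n); pred_n <- integer(n)
  for (r in seq_len(protocol$n_runs)) {
    sp <- cv_split(n, protocol, r)
    res <- tryCatch({
      model <- spec$fit(x[sp$train, , drop = FALSE], y[sp$train],
                        seed = protocol$base_seed + r, h = spec$hyperparameters)
      pred <- spec$predict(model, x[sp$test, , drop = FALSE])
      list(pred = pred)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      runs$failed[r] <- TRUE
      next
    }
    m <- .metrics(y[sp$test], res$pred)
    runs[r, c("mse", "mae", "r2")] <- m
    pred_sum[sp$test] <- pred_sum[sp$test] + res$pred
    pred_sq[sp$test] <- pred_sq[sp$test] + res$pred^2
    pred_n[sp$test] <- pred_n[sp$test] + 1L
  }
  if (any(runs$failed)) {
    warning(sum(runs$failed), " of ", protocol$n_runs,
            " CV runs failed and were excluded")
  }
  ok <- !runs$failed
  mean_pred <- ifelse(pred_n > 0, pred_sum / pred_n, NA_real_)
  var_pred <- ifelse(pred_n > 1,
                     pmax(0, (pred_sq - pred_n * mean_pred^2) / (pred_n - 1)),
                     NA_real_)
  structure(list(
    regressor = spec$name,
    runs = runs,
    mse = mean(runs$mse[ok]), mae = mean(runs$mae[ok]), r2 = mean(runs$r2[ok]),
    per_sample = data.frame(pred_mean = mean_pred, pred_sd = sqrt(var_pred),
                            n_heldout = pred_n),
    protocol = protocol
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> ", x$regressor, ": MSE ", signif(x$mse, 3),
      ", MAE ", signif(x$mae, 3), ", R2 ", signif(x$r2, 3),
      " over ", sum(!x$runs$failed), " runs\n", sep = "")
  invisible(x)
}

# ---- ensembles for screening ----------------------------------------------

#' Fit an ensemble over the CV protocol's training folds
#'
#' @inheritParams evaluate
#' @return a `tpa_ensemble` holding one fitted model per run plus the
#'   training feature names.
#' @export
train_ensemble <- function(x, y, regressor = "xgb", protocol = cv_protocol(),
                           hyper = list()) {
  if (inherits(x, "feature_matrix")) x <- x$x
  spec <- .resolve_regressor(regressor, hyper)
  models <- vector("list", protocol$n_runs)
  for (r in seq_len(protocol$n_runs)) {
    sp <- cv_split(nrow(x), protocol, r)
    models[[r]] <- spec$fit(x[sp$train, , drop = FALSE], y[sp$train],
                            seed = protocol$base_seed + r,
                            h = spec$hyperparameters)
  }
  structure(list(models = models, spec = spec, feature_names = colnames(x),
                 protocol = protocol), class = "tpa_ensemble")
}

#' Ensemble prediction with uncertainty
#'
#' @param object a `tpa_ensemble`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return data.frame with per-sample `lg_tpacs_mean`, `lg_tpacs_sd`, and the
#'   point estimate `tpacs_gm = 10^mean`.
#' @export
predict.tpa_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  miss <- setdiff(object$feature_names, colnames(newdata))
  if (length(miss)) {
    stop("newdata lacks training features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  preds <- vapply(object$models, function(m) object$spec$predict(m, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  mean_lg <- rowMeans(preds)
  sd_lg <- if (ncol(preds) > 1) apply(preds, 1, stats::sd) else rep(0, nrow(preds))
  data.frame(lg_tpacs_mean = mean_lg, lg_tpacs_sd = sd_lg,
             tpacs_gm = 10^mean_lg)
}
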