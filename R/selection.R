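# Feature-selection cascade: combined three-model importance over repeated CV
# splits, backward one-at-a-time elimination, and forward stepwise selection
# seeded with the conjugation length.

.zscore_train_test <- function(xtr, xte = NULL) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  scale_m <- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
  list(train = scale_m(xtr), test = if (!is.null(xte)) scale_m(xte))
}

#' Combined feature importance from three regressor families
#'
#' Over `n_runs` random train/test splits, fits a lasso and two
#' gradient-boosting flavours on z-scored training features; per-method
#' importance is the run-averaged |coefficient| (lasso) or mean |SHAP value|
#' (tree models), each normalized to sum 1; the combined index is their
#' unweighted mean (weights configurable).
#'
#' @param x numeric matrix or `feature_matrix`.
#' @param y targets (lg units).
#' @param n_runs number of CV splits to average over.
#' @param base_seed seed; all splits and fits derive from it.
#' @param test_fraction held-out fraction of each split.
#' @param methods importance methods (registry names; tree entries use SHAP).
#' @param weights combination weights (recycled, renormalized).
#' @param hyper registry hyperparameter overrides.
#' @return an `importance_report`: data.frame of per-method and combined
#'   importances with attributes `n_cv_runs` and `methods_used`.
#' @export
combined_importance <- function(x, y, n_runs = 24, base_seed = 1L,
                                test_fraction = 0.15,
                                methods = c("lasso", "gbrt", "xgb"),
                                weights = NULL, hyper = list()) {
  if (inherits(x, "feature_matrix")) x <- x$x
  stopifnot(n_runs >= 1)
  proto <- cv_protocol(n_runs, test_fraction, base_seed)
  p <- ncol(x)
  acc <- matrix(0, p, length(methods), dimnames = list(colnames(x), methods))
  for (r in seq_len(n_runs)) {
    sp <- cv_split(nrow(x), proto, r)
    z <- .zscore_train_test(x[sp$train, , drop = FALSE])
    xtr <- z$train
    colnames(xtr) <- colnames(x)
    ytr <- y[sp$train]
    for (m in methods) {
      spec <- .resolve_regressor(m, hyper)
      model <- spec$fit(xtr, ytr, seed = base_seed + r, h = spec$hyperparameters)
      imp <- if (!is.null(spec$importance)) {
        spec$importance(model)
      } else if (isTRUE(spec$shap)) {
        colMeans(abs(shap_values(model, xtr)$values))
      } else {
        stop("no importance rule for regressor '", m, "'", call. = FALSE)
      }
      acc[, m] <- acc[, m] + imp
    }
  }
  acc <- acc / n_runs
  sums <- colSums(acc)
  usable <- sums > 0
  if (!all(usable)) {
    warning("method(s) with all-zero importance excluded from the combination: ",
            paste(methods[!usable], collapse = ", "))
  }
  norm <- matrix(0, p, length(methods), dimnames = dimnames(acc))
  norm[, usable] <- sweep(acc[, usable, drop = FALSE], 2, sums[usable], "/")
  w <- if (is.null(weights)) rep(1, sum(usable)) else rep_len(weights, length(methods))[usable]
  w <- w / sum(w)
  combined <- as.numeric(norm[, usable, drop = FALSE] %*% w)
  out <- data.frame(feature = colnames(x), norm, combined = combined,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "n_cv_runs") <- n_runs
  attr(out, "methods_used") <- methods[usable]
  class(out) <- c("importance_report", "data.frame")
  out
}

.trace_row <- function(step, size, feature, action, mse_mean, mse_sd) {
  data.frame(step = step, size = size, feature = feature, action = action,
             mse_mean = mse_mean, mse_sd = mse_sd, stringsAsFactors = FALSE)
}

.trace_mse <- function(x, y, features, regressor, eval_runs, base_seed, hyper) {
  ev <- evaluate(x[, features, drop = FALSE], y, regressor,
                 cv_protocol(eval_runs, 0.15, base_seed), hyper)
  c(mean = ev$mse, sd = stats::sd(ev$runs$mse[!ev$runs$failed]))
}

#' Backward one-at-a-time feature elimination
#'
#' Repeatedly removes the feature with the smallest combined importance,
#' recomputing the importance every `refresh_every` removals
#' (`refresh_every = 1` reproduces strict one-at-a-time refreshing) and
#' recording held-out MSE of the reference regressor at every size.
#'
#' @inheritParams combined_importance
#' @param refresh_every recompute the combined importance after this many
#'   removals.
#' @param stop_size smallest feature-set size to keep.
#' @param regressor reference regressor for the MSE trace.
#' @param eval_runs CV runs per MSE evaluation.
#' @param importance_runs CV runs per importance computation.
#' @return a `selection_trace` data.frame (step, size, feature, action,
#'   mse_mean, mse_sd) with attribute `selected` (features kept at
#'   `stop_size`). Ties on importance remove the later column.
#' @export
backward_eliminate <- function(x, y, refresh_every = 10, stop_size = 1,
                               regressor = "xgb", eval_runs = 8,
                               importance_runs = 24, base_seed = 1L,
                               methods = c("lasso", "gbrt", "xgb"),
                               hyper = list()) {
  if (inherits(x, "feature_matrix")) x <- x$x
  stopifnot(stop_size >= 1)
  current <- colnames(x)
  m0 <- .trace_mse(x, y, current, regressor, eval_runs, base_seed, hyper)
  trace <- .trace_row(0L, length(current), NA_character_, "init", m0["mean"], m0["sd"])
  imp <- NULL
  since_refresh <- Inf
  step <- 0L
  while (length(current) > stop_size) {
    if (since_refresh >= refresh_every) {
      rep_ <- combined_importance(x[, current, drop = FALSE], y,
                                  n_runs = importance_runs,
                                  base_seed = base_seed + step,
                                  methods = methods, hyper = hyper)
      imp <- stats::setNames(rep_$combined, rep_$feature)
      since_refresh <- 0
    }
    cand <- imp[current]
    drop_idx <- max(which(cand == min(cand)))  # later column on ties
    removed <- current[drop_idx]
    current <- setdiff(current, removed)
    step <- step + 1L
    since_refresh <- since_refresh + 1
    m <- .trace_mse(x, y, current, regressor, eval_runs, base_seed + step, hyper)
    trace <- rbind(trace, .trace_row(step, length(current), removed, "remove",
                                     m["mean"], m["sd"]))
  }
  rownames(trace) <- NULL
  attr(trace, "selected") <- current
  class(trace) <- c("selection_trace", "data.frame")
  trace
}

#' Forward stepwise feature selection
#'
#' Starting from the seed features (by default the conjugation length, the
#' most important selected feature), evaluates adding every candidate with
#' the reference regressor under the CV protocol and adds the one with the
#' largest MSE gain; stops when the best gain falls below `tolerance` or the
#' full-matrix MSE (`target_mse`) is reached within `tolerance`.
#'
#' @inheritParams backward_eliminate
#' @param seed_features features to start from (must be matrix columns).
#' @param candidate_pool candidate feature names (default: all others).
#' @param tolerance minimal MSE gain to keep adding.
#' @param target_mse optional reference MSE; selection stops once reached
#'   within `tolerance`.
#' @param max_steps cap on the number of additions.
#' @return a `selection_trace` with attribute `selected`.
#' @export
forward_stepwise <- function(x, y, seed_features = "conju_max_distance",
                             candidate_pool = NULL, tolerance = 0,
                             target_mse = NULL, max_steps = Inf,
                             regressor = "xgb", eval_runs = 8,
                             base_seed = 1L, hyper = list()) {
  if (inherits(x, "feature_matrix")) x <- x$x
  miss <- setdiff(seed_features, colnames(x))
  if (length(miss)) stop("seed feature(s) not in matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(candidate_pool)) candidate_pool <- setdiff(colnames(x), seed_features)
  current <- seed_features
  m0 <- .trace_mse(x, y, current, regressor, eval_runs, base_seed, hyper)
  trace <- .trace_row(0L, length(current), paste(seed_features, collapse = "+"),
                      "init", m0["mean"], m0["sd"])
  best_mse <- m0["mean"]
  step <- 0L
  while (length(candidate_pool) > 0 && step < max_steps && is.finite(tolerance)) {
    if (!is.null(target_mse) && best_mse <= target_mse + tolerance) break
    step <- step + 1L
    res <- vapply(candidate_pool, function(f) {
      .trace_mse(x, y, c(current, f), regressor, eval_runs, base_seed + step, hyper)
    }, c(mean = 0, sd = 0))
    best <- which.min(res["mean", ])
    gain <- best_mse - res["mean", best]
    if (gain < tolerance || gain <= 0) break
    added <- candidate_pool[best]
    current <- c(current, added)
    candidate_pool <- setdiff(candidate_pool, added)
    best_mse <- res["mean", best]
    trace <- rbind(trace, .trace_row(step, length(current), added, "add",
                                     res["mean", best], res["sd", best]))
  }
  rownames(trace) <- NULL
  attr(trace, "selected") <- current
  class(trace) <- c("selection_trace", "data.frame")
  trace
}
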