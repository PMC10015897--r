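# Interpretation: power-law extraction from SHAP attributions, the
# add-one-feature refit protocol, and accumulated local effects.
#
# Because the model works in lg(TPACS) units, an ordinary least-squares fit
# of a feature's SHAP values against the base-10 logarithm of the feature
# value has a slope that is directly the exponent of a power law
# TPACS ~ feature^b.

#' Fit a power law to a feature's SHAP profile
#'
#' @param explanation a `shap_explanation`.
#' @param feature feature name to profile.
#' @param log_transform fit against log10(feature value) (default); when
#'   FALSE the slope is a plain linear effect in lg units per feature unit.
#' @return a `power_law_fit`: list with `exponent` (slope b), `intercept`,
#'   `stderr`, `r_squared`, `n`, `feature`.
#' @export
fit_power_law <- function(explanation, feature = "conju_max_distance",
                          log_transform = TRUE) {
  stopifnot(inherits(explanation, "shap_explanation"))
  if (!feature %in% colnames(explanation$values)) {
    stop("feature '", feature, "' not in explanation", call. = FALSE)
  }
  v <- explanation$feature_values[, feature]
  phi <- explanation$values[, feature]
  if (log_transform) {
    if (any(v <= 0)) stop("log transform requires positive feature values",
                          call. = FALSE)
    v <- log10(v)
  }
  if (length(unique(v)) < 3) {
    stop("degenerate fit: fewer than 3 distinct feature values", call. = FALSE)
  }
  fit <- stats::lm(phi ~ v)
  # a perfectly collinear profile is legitimate here (noiseless oracles)
  sm <- suppressWarnings(summary(fit))
  structure(list(
    exponent = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    stderr = sm$coefficients[2, 2],
    r_squared = sm$r.squared,
    n = length(v),
    feature = feature,
    log_transform = log_transform
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> ", x$feature,
      if (x$log_transform) " (lg-lg)" else " (lg-linear)",
      ": exponent ", signif(x$exponent, 4), " +/- ", signif(x$stderr, 2),
      ", intercept ", signif(x$intercept, 4),
      ", R2 ", signif(x$r_squared, 3), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Add one feature, refit, and explain it
#'
#' Implements the protocol for analyzing a feature outside the selected set:
#' append the column, refit the reference tree model on all samples, and
#' return the SHAP explanation of the enlarged matrix.
#'
#' @param x numeric matrix or `feature_matrix` (the selected features).
#' @param extra single-column matrix or named numeric vector to append.
#' @param y targets (lg units).
#' @param regressor tree-model registry name.
#' @param seed fitting seed.
#' @param hyper registry hyperparameter overrides.
#' @return a `shap_explanation` over the enlarged matrix, with attribute
#'   `extra_feature` naming the appended column.
#' @export
add_feature_and_refit <- function(x, extra, y, regressor = "xgb", seed = 1L,
                                  hyper = list()) {
  if (inherits(x, "feature_matrix")) x <- x$x
  if (is.null(dim(extra))) {
    nm <- deparse(substitute(extra))
    extra <- matrix(extra, ncol = 1, dimnames = list(NULL, nm))
  }
  nm <- colnames(extra)
  if (nm %in% colnames(x)) stop("feature '", nm, "' already in matrix",
                                call. = FALSE)
  x2 <- cbind(x, extra)
  spec <- .resolve_regressor(regressor, hyper)
  if (!isTRUE(spec$shap)) stop("add-and-refit requires a tree regressor",
                               call. = FALSE)
  model <- spec$fit(x2, y, seed = seed, h = spec$hyperparameters)
  ex <- shap_values(model, x2)
  attr(ex, "extra_feature") <- nm
  ex
}

#' First-order accumulated local effects
#'
#' Quantile-binned ALE of one feature: within each bin, the prediction
#' difference between the bin's upper and lower edge is averaged over the
#' samples falling in the bin, the local effects are accumulated, and the
#' curve is centred so its data-weighted mean is zero.
#'
#' @param model fitted model accepted by `predict_fun`, or an `xgb.Booster`.
#' @param x numeric matrix of the data distribution.
#' @param feature feature name.
#' @param n_bins number of quantile bins (>= 2).
#' @param predict_fun function(model, x) -> numeric; defaults to the
#'   double-precision tree walk for boosters.
#' @return an `ale_profile`: list with `edges`, `local_effects`,
#'   `cumulative` (centred), `bin_counts`, `feature`.
#' @export
ale_profile <- function(model, x, feature, n_bins = 20, predict_fun = NULL) {
  if (inherits(x, "feature_matrix")) x <- x$x
  stopifnot(n_bins >= 2, feature %in% colnames(x))
  v <- x[, feature]
  if (length(unique(v)) < 2) stop("degenerate ALE: feature is constant",
                                  call. = FALSE)
  if (is.null(predict_fun)) {
    if (!inherits(model, "xgb.Booster")) {
      stop("supply predict_fun for non-booster models", call. = FALSE)
    }
    predict_fun <- tree_predict
  }
  edges <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  k <- length(edges) - 1
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), k)
  local <- numeric(k)
  counts <- integer(k)
  for (j in seq_len(k)) {
    idx <- which(bin == j)
    counts[j] <- length(idx)
    if (!length(idx)) next
    xu <- x[idx, , drop = FALSE]; xu[, feature] <- edges[j + 1]
    xl <- x[idx, , drop = FALSE]; xl[, feature] <- edges[j]
    local[j] <- mean(predict_fun(model, xu) - predict_fun(model, xl))
  }
  cum <- cumsum(local)
  centre <- sum(counts * cum) / sum(counts)
  structure(list(edges = edges, local_effects = local,
                 cumulative = cum - centre, bin_counts = counts,
                 feature = feature), class = "ale_profile")
}

#' Slope of an ALE curve
#'
#' Weighted least-squares slope of the centred ALE curve against the bin
#' upper edges (weights = bin counts); for a model additive and linear in the
#' feature this recovers the linear coefficient.
#'
#' @param profile an `ale_profile`.
#' @param log_transform regress against log10 of the edges.
#' @return numeric slope.
#' @export
ale_slope <- function(profile, log_transform = FALSE) {
  xx <- profile$edges[-1]
  if (log_transform) xx <- log10(xx)
  ok <- profile$bin_counts > 0
  unname(stats::coef(stats::lm(profile$cumulative[ok] ~ xx[ok],
                               weights = profile$bin_counts[ok]))[2])
}
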