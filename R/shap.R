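# SHAP attribution for tree ensembles.
#
# Tree structures are extracted from fitted xgboost boosters and attributed
# in double precision by the compiled exact TreeSHAP routine, so the
# additivity identity (base value + sum of attributions = prediction through
# the same trees) holds to numerical precision rather than to float32.

#' @useDynLib tpascreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# flatten an xgboost booster into per-tree node arrays (0-based children)
.parse_xgb_trees <- function(model, feature_names) {
  dt <- xgboost::xgb.model.dt.tree(model = model)
  dt <- as.data.frame(dt)
  lapply(split(dt, dt$Tree), function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    id2idx <- stats::setNames(seq_len(nrow(tr)) - 1L, tr$ID)
    leaf <- tr$Feature == "Leaf"
    feat <- rep(-1L, nrow(tr))
    if (any(!leaf)) {
      f <- tr$Feature[!leaf]
      idx <- match(f, feature_names)
      # xgboost falls back to "f<k>" / plain indices without stored names
      if (anyNA(idx)) idx <- as.integer(sub("^f", "", f)) + 1L
      if (anyNA(idx)) stop("cannot map tree split features to matrix columns")
      feat[!leaf] <- idx - 1L
    }
    list(
      feature = as.integer(feat),
      threshold = as.numeric(ifelse(leaf, 0, as.numeric(tr$Split))),
      yes = as.integer(ifelse(leaf, 0L, unname(id2idx[tr$Yes]))),
      no = as.integer(ifelse(leaf, 0L, unname(id2idx[tr$No]))),
      missing = as.integer(ifelse(leaf, 0L, unname(id2idx[tr$Missing]))),
      value = as.numeric(ifelse(leaf, as.numeric(tr$Gain), 0)),
      cover = as.numeric(tr$Cover)
    )
  })
}

.xgb_base_score <- function(model) {
  cfg <- xgboost::xgb.config(model)
  as.numeric(cfg$learner$learner_model_param$base_score)
}

#' Exact SHAP values for a fitted tree ensemble
#'
#' Computes per-sample, per-feature Shapley attributions with the exact
#' path-dependent tree algorithm (cover-weighted conditional expectations).
#' Only tree ensembles are supported; sampling approximations for other model
#' classes are out of scope.
#'
#' @param model a fitted `xgb.Booster` (e.g. from the `gbrt`/`xgb` registry
#'   entries).
#' @param x numeric matrix (or `feature_matrix`) to explain; columns must
#'   match the training features.
#' @return a `shap_explanation`: list with `values` (samples x features),
#'   `base_value`, `feature_values` (the inputs), and `prediction`
#'   (`base_value + rowSums(values)`, the double-precision tree walk).
#' @export
shap_values <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- x$x
  if (!inherits(model, "xgb.Booster")) {
    stop("exact tree SHAP requires a tree-ensemble model (xgb.Booster); ",
         "got ", paste(class(model), collapse = "/"), call. = FALSE)
  }
  stopifnot(is.matrix(x))
  trees <- .parse_xgb_trees(model, colnames(x))
  base <- .xgb_base_score(model)
  res <- .treeshap_cpp(trees, x, base)
  phi <- res$phi
  colnames(phi) <- colnames(x)
  rownames(phi) <- rownames(x)
  pred <- res$base_value + rowSums(phi)
  structure(list(values = phi, base_value = res$base_value,
                 feature_values = x, prediction = pred),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  imp <- sort(colMeans(abs(x$values)), decreasing = TRUE)
  cat("<shap_explanation> ", nrow(x$values), " samples x ", ncol(x$values),
      " features, base value ", signif(x$base_value, 4), "\n", sep = "")
  cat("  top mean |phi|: ",
      paste(names(imp)[seq_len(min(5, length(imp)))],
            signif(imp[seq_len(min(5, length(imp)))], 3),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# double-precision prediction through the parsed trees (used by tests and by
# the additivity check)
tree_predict <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- x$x
  trees <- .parse_xgb_trees(model, colnames(x))
  .treepredict_cpp(trees, x, .xgb_base_score(model))
}

#' Export a SHAP explanation as a tidy table
#' @param explanation a `shap_explanation`.
#' @return data.frame with sample, feature, feature_value, phi.
#' @export
shap_table <- function(explanation) {
  v <- explanation$values
  data.frame(
    sample = rep(rownames(v) %||% seq_len(nrow(v)), ncol(v)),
    feature = rep(colnames(v), each = nrow(v)),
    feature_value = as.vector(explanation$feature_values[, colnames(v)]),
    phi = as.vector(v),
    stringsAsFactors = FALSE
  )
}
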