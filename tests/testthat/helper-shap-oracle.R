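# Independent brute-force Shapley oracle for tree ensembles: conditional
# expectations by cover-weighted tree traversal, exhaustive enumeration of
# feature coalitions. Exponential in the number of features; used only on
# small models.

# xgboost stores features and thresholds in float32; replicate its comparison
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric",
          size = 4, n = length(v))
}

oracle_tree_expected <- function(tree, x, S) {
  rec <- function(node) {
    if (tree$feature[node + 1] < 0) return(tree$value[node + 1])
    f <- tree$feature[node + 1] + 1
    if (f %in% S) {
      if (as_float32(x[f]) < as_float32(tree$threshold[node + 1])) {
        rec(tree$yes[node + 1])
      } else {
        rec(tree$no[node + 1])
      }
    } else {
      wy <- tree$cover[tree$yes[node + 1] + 1]
      wn <- tree$cover[tree$no[node + 1] + 1]
      (wy * rec(tree$yes[node + 1]) + wn * rec(tree$no[node + 1])) / (wy + wn)
    }
  }
  rec(0)
}

oracle_shapley <- function(trees, x, p) {
  phi <- numeric(p)
  for (tree in trees) {
    for (j in seq_len(p)) {
      others <- setdiff(seq_len(p), j)
      for (k in 0:length(others)) {
        subsets <- if (k == 0) list(integer(0)) else
          asplit(utils::combn(others, k), 2)
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        for (S in subsets) {
          phi[j] <- phi[j] + w * (oracle_tree_expected(tree, x, c(S, j)) -
                                    oracle_tree_expected(tree, x, S))
        }
      }
    }
  }
  phi
}

fit_small_booster <- function(x, y, max_depth = 3, nrounds = 5, eta = 0.3,
                              base_score = mean(y), seed = 1) {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(max_depth = max_depth, eta = eta, base_score = base_score,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0
  )
}
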