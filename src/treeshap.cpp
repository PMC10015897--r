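// Exact path-dependent TreeSHAP for additive tree ensembles, in double
// precision. Follows the polynomial-time algorithm of Lundberg et al.
// (Tree SHAP); conditional expectations use the tree's cover weights, so the
// attributions agree with brute-force coalition enumeration over the same
// trees to machine precision.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct PE {
  int feature;
  double zero_frac;
  double one_frac;
  double pweight;
};

static void extend_path(std::vector<PE> &path, int depth, double zero_frac,
                        double one_frac, int feature) {
  path[depth] = {feature, zero_frac, one_frac, depth == 0 ? 1.0 : 0.0};
  for (int i = depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_frac * path[i].pweight * (i + 1.0) / (depth + 1.0);
    path[i].pweight = zero_frac * path[i].pweight * (depth - i) / (depth + 1.0);
  }
}

static void unwind_path(std::vector<PE> &path, int depth, int index) {
  const double one_frac = path[index].one_frac;
  const double zero_frac = path[index].zero_frac;
  double next_one = path[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_frac != 0.0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one * (depth + 1.0) / ((i + 1.0) * one_frac);
      next_one = tmp - path[i].pweight * zero_frac * (depth - i) / (depth + 1.0);
    } else {
      path[i].pweight = path[i].pweight * (depth + 1.0) / (zero_frac * (depth - i));
    }
  }
  for (int i = index; i < depth; ++i) {
    path[i].feature = path[i + 1].feature;
    path[i].zero_frac = path[i + 1].zero_frac;
    path[i].one_frac = path[i + 1].one_frac;
  }
}

static double unwound_sum(const std::vector<PE> &path, int depth, int index) {
  const double one_frac = path[index].one_frac;
  const double zero_frac = path[index].zero_frac;
  double next_one = path[depth].pweight;
  double total = 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    if (one_frac != 0.0) {
      const double tmp = next_one * (depth + 1.0) / ((i + 1.0) * one_frac);
      total += tmp;
      next_one = path[i].pweight - tmp * zero_frac * (depth - i) / (depth + 1.0);
    } else {
      total += path[i].pweight * (depth + 1.0) / (zero_frac * (depth - i));
    }
  }
  return total;
}

struct Tree {
  const int *feature;       // -1 for leaf
  const double *threshold;
  const int *yes;           // 0-based node index
  const int *no;
  const int *missing;
  const double *value;
  const double *cover;
};

static void tree_recurse(const Tree &tr, const NumericMatrix &X, int row,
                         NumericVector::iterator phi, int node,
                         std::vector<PE> path, int depth, double parent_zero,
                         double parent_one, int parent_feature) {
  if ((int)path.size() < depth + 1) path.resize(depth + 1);
  extend_path(path, depth, parent_zero, parent_one, parent_feature);
  if (tr.feature[node] < 0) {
    for (int i = 1; i <= depth; ++i) {
      const double w = unwound_sum(path, depth, i);
      phi[path[i].feature] +=
          w * (path[i].one_frac - path[i].zero_frac) * tr.value[node];
    }
    return;
  }
  const int f = tr.feature[node];
  const double xv = X(row, f);
  int hot, cold;
  if (ISNAN(xv)) {
    hot = tr.missing[node];
    cold = (hot == tr.yes[node]) ? tr.no[node] : tr.yes[node];
  } else if ((float)xv < (float)tr.threshold[node]) {
    // xgboost stores thresholds and compares features in float32

    hot = tr.yes[node];
    cold = tr.no[node];
  } else {
    hot = tr.no[node];
    cold = tr.yes[node];
  }
  double incoming_zero = 1.0, incoming_one = 1.0;
  int found = -1;
  for (int i = 1; i <= depth; ++i) {
    if (path[i].feature == f) { found = i; break; }
  }
  if (found >= 0) {
    incoming_zero = path[found].zero_frac;
    incoming_one = path[found].one_frac;
    unwind_path(path, depth, found);
    depth -= 1;
  }
  const double hot_zero = tr.cover[hot] / tr.cover[node];
  const double cold_zero = tr.cover[cold] / tr.cover[node];
  tree_recurse(tr, X, row, phi, hot, path, depth + 1,
               hot_zero * incoming_zero, incoming_one, f);
  tree_recurse(tr, X, row, phi, cold, path, depth + 1,
               cold_zero * incoming_zero, 0.0, f);
}

static double tree_expected(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  const double wy = tr.cover[tr.yes[node]];
  const double wn = tr.cover[tr.no[node]];
  return (wy * tree_expected(tr, tr.yes[node]) +
          wn * tree_expected(tr, tr.no[node])) / (wy + wn);
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(List trees, NumericMatrix X, double base_score) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  double expected = base_score;
  std::vector<Tree> parsed;
  std::vector<List> keep;
  for (int t = 0; t < trees.size(); ++t) {
    List tl = trees[t];
    keep.push_back(tl);
    Tree tr;
    tr.feature = INTEGER(((SEXP)tl["feature"]));
    tr.threshold = REAL(((SEXP)tl["threshold"]));
    tr.yes = INTEGER(((SEXP)tl["yes"]));
    tr.no = INTEGER(((SEXP)tl["no"]));
    tr.missing = INTEGER(((SEXP)tl["missing"]));
    tr.value = REAL(((SEXP)tl["value"]));
    tr.cover = REAL(((SEXP)tl["cover"]));
    parsed.push_back(tr);
    expected += tree_expected(tr, 0);
  }
  NumericVector phirow(p);
  for (int i = 0; i < n; ++i) {
    std::fill(phirow.begin(), phirow.end(), 0.0);
    for (size_t t = 0; t < parsed.size(); ++t) {
      std::vector<PE> path;
      tree_recurse(parsed[t], X, i, phirow.begin(), 0, path, 0, 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = phirow[j];
  }
  return List::create(_["phi"] = phi, _["base_value"] = expected);
}

// Double-precision prediction through the parsed trees (reference for the
// additivity invariant).
// [[Rcpp::export(name = ".treepredict_cpp")]]
NumericVector treepredict_cpp(List trees, NumericMatrix X, double base_score) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  for (int t = 0; t < trees.size(); ++t) {
    List tl = trees[t];
    const int *feature = INTEGER(((SEXP)tl["feature"]));
    const double *threshold = REAL(((SEXP)tl["threshold"]));
    const int *yes = INTEGER(((SEXP)tl["yes"]));
    const int *no = INTEGER(((SEXP)tl["no"]));
    const int *missing = INTEGER(((SEXP)tl["missing"]));
    const double *value = REAL(((SEXP)tl["value"]));
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        const double xv = X(i, feature[node]);
        if (ISNAN(xv)) node = missing[node];
        else node = ((float)xv < (float)threshold[node]) ? yes[node] : no[node];
      }
      out[i] += value[node];
    }
  }
  return out;
}
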