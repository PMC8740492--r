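// Path-dependent tree-path Shapley attributions for binary decision trees.
//
// Implements the polynomial-time algorithm that tracks, for every unique
// feature on the current root-to-node path, the fraction of feature subsets
// that flow down the path with the feature included ("one fraction") or
// excluded ("zero fraction", weighted by node covers), together with the
// permutation weights of all subset sizes.  Summing the unwound weights at a
// leaf yields each feature's exact Shapley value with respect to the
// cover-weighted conditional expectation of the tree.
//
// Trees are passed as flat arrays (left/right child, split feature, split
// threshold, leaf value); covers are computed here by routing a background
// matrix through each tree, so they always satisfy cover(parent) =
// cover(left) + cover(right).  Numeric splits send x <= threshold left.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> left, right, feature;   // 0-based; -1 = none / leaf
  std::vector<double> threshold, value, cover;
};

struct PathElement {
  int feature;      // -1 for the root sentinel
  double zero;      // subset-excluded flow fraction (cover-weighted)
  double one;       // subset-included flow fraction (0/1 path indicator)
  double weight;    // summed permutation weights
};

void extend_path(std::vector<PathElement>& m, double pz, double po, int pi) {
  const int l = static_cast<int>(m.size());
  PathElement e;
  e.feature = pi; e.zero = pz; e.one = po; e.weight = (l == 0 ? 1.0 : 0.0);
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].weight += po * m[i].weight * (i + 1.0) / (l + 1.0);
    m[i].weight = pz * m[i].weight * (l - i) / (l + 1.0);
  }
}

void unwind_path(std::vector<PathElement>& m, int i) {
  const int l = static_cast<int>(m.size()) - 1;
  const double one = m[i].one, zero = m[i].zero;
  double n = m[l].weight;
  if (one == 0 && zero == 0) {
    // the element zeroed every weight on extension; nothing can flow
    for (int j = i; j < l; ++j) {
      m[j].feature = m[j + 1].feature;
      m[j].zero = m[j + 1].zero;
      m[j].one = m[j + 1].one;
    }
    m.pop_back();
    return;
  }
  if (one != 0) {
    for (int j = l - 1; j >= 0; --j) {
      const double t = m[j].weight;
      m[j].weight = n * (l + 1.0) / ((j + 1.0) * one);
      n = t - m[j].weight * zero * (l - j) / (l + 1.0);
    }
  } else {
    for (int j = l - 1; j >= 0; --j)
      m[j].weight = m[j].weight * (l + 1.0) / (zero * (l - j));
  }
  for (int j = i; j < l; ++j) {
    m[j].feature = m[j + 1].feature;
    m[j].zero = m[j + 1].zero;
    m[j].one = m[j + 1].one;
  }
  m.pop_back();
}

double unwound_path_sum(const std::vector<PathElement>& m, int i) {
  const int l = static_cast<int>(m.size()) - 1;
  const double one = m[i].one, zero = m[i].zero;
  if (one == 0 && zero == 0) return 0.0;
  double total = 0.0;
  if (one != 0) {
    double n = m[l].weight;
    for (int j = l - 1; j >= 0; --j) {
      const double t = n / ((j + 1.0) * one);
      total += t;
      n = m[j].weight - t * zero * (l - j);
    }
  } else {
    for (int j = l - 1; j >= 0; --j)
      total += m[j].weight / (zero * (l - j));
  }
  return total * (l + 1.0);
}

void recurse(const Tree& tree, const double* x, double* phi,
             int node, std::vector<PathElement> m,
             double pz, double po, int pi) {
  extend_path(m, pz, po, pi);
  const int depth = static_cast<int>(m.size()) - 1;

  if (tree.feature[node] < 0) {  // leaf
    for (int i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(m, i);
      phi[m[i].feature] += w * (m[i].one - m[i].zero) * tree.value[node];
    }
    return;
  }

  const int f = tree.feature[node];
  const int lo = tree.left[node], hi = tree.right[node];
  const bool go_left = x[f] <= tree.threshold[node];
  const int hot = go_left ? lo : hi;
  const int cold = go_left ? hi : lo;
  const double w = tree.cover[node];
  const double hot_zero = (w > 0) ? tree.cover[hot] / w : 0.0;
  const double cold_zero = (w > 0) ? tree.cover[cold] / w : 0.0;

  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int j = 1; j <= depth; ++j)
    if (m[j].feature == f) { k = j; break; }
  if (k >= 0) {
    iz = m[k].zero;
    io = m[k].one;
    unwind_path(m, k);
  }

  recurse(tree, x, phi, hot, m, hot_zero * iz, io, f);
  // a branch no background row reaches has probability zero under the
  // cover distribution; descending into it would divide by that zero
  if (tree.cover[cold] > 0)
    recurse(tree, x, phi, cold, m, cold_zero * iz, 0.0, f);
}

Tree build_tree(const List& tr, const NumericMatrix& background) {
  Tree t;
  IntegerVector left = tr["left"], right = tr["right"], feature = tr["feature"];
  NumericVector threshold = tr["threshold"], value = tr["value"];
  const int n_nodes = left.size();
  t.left.assign(left.begin(), left.end());
  t.right.assign(right.begin(), right.end());
  t.feature.assign(feature.begin(), feature.end());
  t.threshold.assign(threshold.begin(), threshold.end());
  t.value.assign(value.begin(), value.end());
  t.cover.assign(n_nodes, 0.0);

  // route every background row from the root to its leaf
  const int nb = background.nrow();
  for (int r = 0; r < nb; ++r) {
    int node = 0;
    t.cover[0] += 1.0;
    while (t.feature[node] >= 0) {
      node = (background(r, t.feature[node]) <= t.threshold[node])
                 ? t.left[node] : t.right[node];
      t.cover[node] += 1.0;
    }
  }
  if (t.cover[0] <= 0)
    stop("background matrix is empty; covers cannot be computed");
  return t;
}

double expected_value(const Tree& t) {
  double total = 0.0;
  for (size_t i = 0; i < t.value.size(); ++i)
    if (t.feature[i] < 0) total += t.value[i] * t.cover[i];
  return total / t.cover[0];
}

}  // namespace

//' @title Forest tree-path Shapley values (internal)
//' @description Computes per-row Shapley attributions for an ensemble of
//'   binary trees, averaging over trees, with covers taken from a background
//'   matrix. Not exported to users; see [attributions()].
//' @noRd
// [[Rcpp::export]]
List cpp_forest_shap(List trees, NumericMatrix x, NumericMatrix background) {
  const int n = x.nrow(), p = x.ncol(), ntree = trees.size();
  if (ntree == 0) stop("no trees supplied");
  if (background.ncol() != p) stop("background and x column counts differ");

  NumericMatrix phi(n, p);
  double base = 0.0;
  std::vector<double> row(p), phirow(p);

  for (int k = 0; k < ntree; ++k) {
    Tree t = build_tree(trees[k], background);
    base += expected_value(t);
    for (int r = 0; r < n; ++r) {
      for (int j = 0; j < p; ++j) { row[j] = x(r, j); phirow[j] = 0.0; }
      std::vector<PathElement> m;
      m.reserve(64);
      recurse(t, row.data(), phirow.data(), 0, m, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(r, j) += phirow[j];
    }
  }

  // forest output is the mean of tree outputs
  for (int r = 0; r < n; ++r)
    for (int j = 0; j < p; ++j) phi(r, j) /= ntree;
  base /= ntree;

  return List::create(_["phi"] = phi, _["base_value"] = base);
}

//' @title Tree-ensemble prediction under routing (internal)
//' @description Mean leaf value across trees for each row of `x`, using the
//'   same routing rule as the attribution code; used to verify local
//'   accuracy independently of the forest's own predict method.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_forest_value(List trees, NumericMatrix x) {
  const int n = x.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int k = 0; k < ntree; ++k) {
    List tr = trees[k];
    IntegerVector left = tr["left"], right = tr["right"], feature = tr["feature"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int r = 0; r < n; ++r) {
      int node = 0;
      while (feature[node] >= 0)
        node = (x(r, feature[node]) <= threshold[node]) ? left[node] : right[node];
      out[r] += value[node];
    }
  }
  for (int r = 0; r < n; ++r) out[r] /= ntree;
  return out;
}
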