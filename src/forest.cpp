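// Classification random forest for binary outcomes.
//
// Small-cohort setting: n is tens of rows, p up to a few thousand
// features.  Trees are grown to purity (min node size 1) on bootstrap
// samples, splitting on the Gini criterion with `mtry` candidate
// features per node.  Leaf prediction is the positive-class fraction of
// the bootstrap rows in the leaf; forest probability is the mean over
// trees.  A private mt19937 stream keyed by `seed` makes fits
// reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNode {
  int feature;       // 0-based split feature, -1 for leaf
  double threshold;  // go left when x <= threshold
  int left;
  int right;
  double value;      // leaf: positive-class fraction
  double n_node;     // bootstrap rows reaching the node
};

inline double gini_impurity(double n, double npos) {
  if (n <= 0.0) return 0.0;
  const double p = npos / n;
  return 2.0 * p * (1.0 - p);
}

struct TreeBuilder {
  const NumericMatrix& x;
  const IntegerVector& y;
  int mtry;
  int min_node;
  std::mt19937& rng;
  std::vector<TreeNode> nodes;
  std::vector<double>& importance;  // accumulated n_node * gini decrease
  std::vector<int> feat_pool;

  TreeBuilder(const NumericMatrix& x_, const IntegerVector& y_, int mtry_,
              int min_node_, std::mt19937& rng_, std::vector<double>& imp_)
      : x(x_), y(y_), mtry(mtry_), min_node(min_node_), rng(rng_),
        importance(imp_), feat_pool(x_.ncol()) {
    for (int j = 0; j < x_.ncol(); ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx, int lo, int hi) {
    const int n = hi - lo;
    double npos = 0.0;
    for (int i = lo; i < hi; ++i) npos += y[idx[i]];

    const int me = static_cast<int>(nodes.size());
    nodes.push_back(TreeNode{-1, 0.0, -1, -1, npos / n,
                             static_cast<double>(n)});

    const double imp_parent = gini_impurity(n, npos);
    if (n <= min_node || imp_parent <= 0.0) return me;

    // sample mtry features without replacement (partial Fisher-Yates)
    int best_f = -1;
    double best_thr = 0.0, best_dec = 1e-12;
    const int p = x.ncol();
    for (int k = 0; k < mtry; ++k) {
      std::uniform_int_distribution<int> pick(k, p - 1);
      std::swap(feat_pool[k], feat_pool[pick(rng)]);
      const int f = feat_pool[k];

      // sort node rows by feature value
      std::sort(idx.begin() + lo, idx.begin() + hi,
                [&](int a, int b) { return x(a, f) < x(b, f); });
      double nl = 0.0, posl = 0.0;
      for (int i = lo; i < hi - 1; ++i) {
        nl += 1.0;
        posl += y[idx[i]];
        if (x(idx[i], f) == x(idx[i + 1], f)) continue;
        const double nr = n - nl, posr = npos - posl;
        const double child =
            (nl * gini_impurity(nl, posl) + nr * gini_impurity(nr, posr)) / n;
        const double dec = imp_parent - child;
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (x(idx[i], f) + x(idx[i + 1], f));
        }
      }
    }

    if (best_f < 0) return me;  // no admissible split: leaf

    importance[best_f] += n * best_dec;

    // partition rows around the chosen split
    std::vector<int> lhs, rhs;
    lhs.reserve(n);
    rhs.reserve(n);
    for (int i = lo; i < hi; ++i) {
      if (x(idx[i], best_f) <= best_thr)
        lhs.push_back(idx[i]);
      else
        rhs.push_back(idx[i]);
    }
    std::copy(lhs.begin(), lhs.end(), idx.begin() + lo);
    std::copy(rhs.begin(), rhs.end(), idx.begin() + lo + lhs.size());
    const int mid = lo + static_cast<int>(lhs.size());

    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    const int l = build(idx, lo, mid);
    nodes[me].left = l;
    const int r = build(idx, mid, hi);
    nodes[me].right = r;
    return me;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix x, IntegerVector y, int ntree, int mtry,
                int min_node, int seed) {
  const int n = x.nrow(), p = x.ncol();
  if (n < 2) stop("need at least two rows to fit a forest");
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, n_features]");
  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::uniform_int_distribution<int> row(0, n - 1);

  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = row(rng);
    TreeBuilder tb(x, y, mtry, min_node, rng, importance);
    tb.build(idx, 0, n);

    const int m = static_cast<int>(tb.nodes.size());
    NumericMatrix enc(m, 5);
    for (int i = 0; i < m; ++i) {
      enc(i, 0) = tb.nodes[i].feature;
      enc(i, 1) = tb.nodes[i].threshold;
      enc(i, 2) = tb.nodes[i].left;
      enc(i, 3) = tb.nodes[i].right;
      enc(i, 4) = tb.nodes[i].value;
    }
    trees[t] = enc;
  }
  for (int j = 0; j < p; ++j) importance[j] /= ntree;
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix x) {
  const int n = x.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix enc = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (enc(node, 0) >= 0) {
        const int f = static_cast<int>(enc(node, 0));
        node = (x(i, f) <= enc(node, 1)) ? static_cast<int>(enc(node, 2))
                                         : static_cast<int>(enc(node, 3));
      }
      out[i] += enc(node, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// Predict the forest on `x` with column `col` randomly permuted,
// `n_perm` times: the workhorse of permutation importance, where
// per-permutation round trips through R would dominate the runtime.
// Returns an n x n_perm matrix of positive-class probabilities.
// [[Rcpp::export(name = ".rf_predict_perm_cpp")]]
NumericMatrix rf_predict_perm_cpp(List trees, NumericMatrix x, int col,
                                  int n_perm, int seed) {
  const int n = x.nrow(), ntree = trees.size();
  NumericMatrix out(n, n_perm);
  NumericMatrix xp(clone(x));
  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::vector<double> colvals(n);
  for (int i = 0; i < n; ++i) colvals[i] = x(i, col);
  for (int s = 0; s < n_perm; ++s) {
    // Fisher-Yates shuffle of the original column values
    std::vector<double> shuf(colvals);
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> pick(0, i);
      std::swap(shuf[i], shuf[pick(rng)]);
    }
    for (int i = 0; i < n; ++i) xp(i, col) = shuf[i];
    for (int t = 0; t < ntree; ++t) {
      NumericMatrix enc = trees[t];
      for (int i = 0; i < n; ++i) {
        int node = 0;
        while (enc(node, 0) >= 0) {
          const int f = static_cast<int>(enc(node, 0));
          node = (xp(i, f) <= enc(node, 1)) ? static_cast<int>(enc(node, 2))
                                            : static_cast<int>(enc(node, 3));
        }
        out(i, s) += enc(node, 4);
      }
    }
  }
  for (int s = 0; s < n_perm; ++s)
    for (int i = 0; i < n; ++i) out(i, s) /= ntree;
  return out;
}
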