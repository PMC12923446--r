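// Weighted regression trees for GENIE3-style network inference.
//
// Trees are grown CART-style: at each node a random subset of n_test input
// columns is drawn (without replacement, from R's RNG so set.seed() governs
// everything), candidate thresholds are midpoints between consecutive
// distinct sorted values, and the split maximising the weighted variance
// reduction is taken. Ties go to the lowest feature index, then the smallest
// threshold, so tree growth is deterministic given the feature draws.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct FlatTree {
  // parallel arrays; node 0 is the root
  std::vector<int> feature;       // -1 for leaves (0-based column otherwise)
  std::vector<double> threshold;  // NA for leaves
  std::vector<int> left, right;   // -1 for leaves
  std::vector<double> value;      // weighted mean of outputs at the node
  std::vector<double> reduction;  // weighted variance reduction of the split
  std::vector<double> node_w;     // total example weight at the node

  int new_node(double val, double w) {
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(val);
    reduction.push_back(0.0);
    node_w.push_back(w);
    return (int)feature.size() - 1;
  }
};

// draw `k` distinct integers from 0..(p-1) via partial Fisher-Yates on R's RNG
void sample_features(int p, int k, std::vector<int> &pool, std::vector<int> &out) {
  pool.resize(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)std::floor(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
  std::sort(out.begin(), out.end());  // lowest-index tie break
}

struct Item { double x, y, w; int id; };

class Builder {
public:
  Builder(const NumericMatrix &X, const NumericVector &y,
          const NumericVector &w, int n_test, int max_height)
      : X_(X), y_(y), w_(w), n_test_(n_test), max_height_(max_height) {}

  FlatTree tree;

  int grow(std::vector<int> &idx, int height) {
    const int n = (int)idx.size();
    double W = 0.0, sy = 0.0, sy2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double wi = w_[idx[i]], yi = y_[idx[i]];
      W += wi;
      sy += wi * yi;
      sy2 += wi * yi * yi;
    }
    const double mean = sy / W;
    const double sse = std::max(0.0, sy2 - sy * sy / W);
    int node = tree.new_node(mean, W);

    if (n < 2 || height >= max_height_ || sse <= 1e-12 * (1.0 + sy2))
      return node;

    sample_features((int)X_.ncol(), n_test_, pool_, feats_);

    int best_f = -1, best_cut = -1;
    double best_gain = 0.0, best_thr = 0.0;
    std::vector<Item> items(n), best_items;
    for (size_t fi = 0; fi < feats_.size(); ++fi) {
      const int f = feats_[fi];
      const double *col = &X_(0, f);
      for (int i = 0; i < n; ++i) {
        const int r = idx[i];
        items[i] = {col[r], y_[r], w_[r], r};
      }
      // stable by x: ties keep input order, so sums over tied blocks are
      // reproducible and no threshold falls inside a block
      std::stable_sort(items.begin(), items.end(),
                       [](const Item &a, const Item &b) { return a.x < b.x; });
      double wl = 0.0, syl = 0.0, sy2l = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        wl += items[i].w;
        syl += items[i].w * items[i].y;
        sy2l += items[i].w * items[i].y * items[i].y;
        const double xa = items[i].x, xb = items[i + 1].x;
        if (xb <= xa) continue;  // no threshold inside a tied block
        const double wr = W - wl;
        if (wl <= 0.0 || wr <= 0.0) continue;
        const double sser = std::max(0.0, (sy2 - sy2l) -
                                     (sy - syl) * (sy - syl) / wr);
        const double ssel = std::max(0.0, sy2l - syl * syl / wl);
        const double gain = sse - ssel - sser;  // = W * variance reduction
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xa + xb);
          best_cut = i;
          best_items = items;
        }
      }
    }

    if (best_f < 0) return node;  // no admissible split among sampled features

    std::vector<int> lidx(best_cut + 1), ridx(n - best_cut - 1);
    for (int i = 0; i <= best_cut; ++i) lidx[i] = best_items[i].id;
    for (int i = best_cut + 1; i < n; ++i)
      ridx[i - best_cut - 1] = best_items[i].id;
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.reduction[node] = best_gain / W;
    int l = grow(lidx, height + 1);
    int r = grow(ridx, height + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }

private:
  const NumericMatrix &X_;
  const NumericVector &y_;
  const NumericVector &w_;
  int n_test_, max_height_;
  std::vector<int> pool_, feats_;
};

List tree_to_list(const FlatTree &t, double w_scale) {
  const int m = (int)t.feature.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m), reduction(m), node_w(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = t.feature[i] < 0 ? NA_INTEGER : t.feature[i] + 1;  // 1-based
    threshold[i] = t.threshold[i];
    left[i] = t.left[i] < 0 ? NA_INTEGER : t.left[i] + 1;
    right[i] = t.right[i] < 0 ? NA_INTEGER : t.right[i] + 1;
    value[i] = t.value[i];
    reduction[i] = t.reduction[i];
    node_w[i] = t.node_w[i] * w_scale;  // back on the caller's weight scale
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value, _["reduction"] = reduction,
                      _["node_w"] = node_w);
}

struct TreeView {
  IntegerVector feature, left, right;
  NumericVector threshold, value;
  explicit TreeView(const List &t)
      : feature(t["feature"]), left(t["left"]), right(t["right"]),
        threshold(t["threshold"]), value(t["value"]) {}

  // predict one row of X, optionally overriding column `swap_col` (0-based)
  // with `swap_val`; swap_col = -1 disables the override
  double predict_row(const NumericMatrix &X, int row, int swap_col,
                     double swap_val) const {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      const int f = feature[node] - 1;
      const double x = (f == swap_col) ? swap_val : X(row, f);
      node = (x <= threshold[node] ? left[node] : right[node]) - 1;
    }
    return value[node];
  }
};

}  // namespace

// normalise weights to mean 1: only relative weights matter to the tree,
// and this makes "all weights equal to a constant c" bit-identical to
// unit weights
NumericVector normalise_w(const NumericVector &w, double &w_scale) {
  const int n = w.size();
  NumericVector out(n);
  bool constant = true;
  for (int i = 1; i < n; ++i)
    if (w[i] != w[0]) { constant = false; break; }
  if (constant) {
    std::fill(out.begin(), out.end(), 1.0);
    w_scale = w[0];
    return out;
  }
  double s = 0.0;
  for (double wi : w) s += wi;
  w_scale = s / n;
  for (int i = 0; i < n; ++i) out[i] = w[i] * (n / s);
  return out;
}

// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, NumericVector y, NumericVector w,
                  int n_test, int max_height) {
  double w_scale = 1.0;
  NumericVector wn = normalise_w(w, w_scale);
  Builder b(X, y, wn, n_test, max_height);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  b.grow(idx, 1);
  return tree_to_list(b.tree, w_scale);
}

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, NumericVector w,
                    int n_trees, int n_test, int max_height) {
  double w_scale = 1.0;
  NumericVector wn = normalise_w(w, w_scale);
  List out(n_trees);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  for (int t = 0; t < n_trees; ++t) {
    Builder b(X, y, wn, n_test, max_height);
    std::vector<int> id2(idx);
    b.grow(id2, 1);
    out[t] = tree_to_list(b.tree, w_scale);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  TreeView tv(tree);
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = tv.predict_row(X, i, -1, 0.0);
  return out;
}

// Permutation (random-input) importance.
//
// trees:    list of trees; idx_list[t] gives the 1-based rows of X forming
//           tree t's own evaluation set (its bagging sample).
// n_rnd:    independent repetitions; a fresh permutation is drawn from R's
//           RNG for every (repetition, tree, feature) triple.
// Returns the per-feature increase in weighted MSE over the unpermuted
// baseline, averaged over trees and repetitions.
// [[Rcpp::export]]
NumericVector cpp_perm_importance(List trees, NumericMatrix X, NumericVector y,
                                  NumericVector w, List idx_list, int n_rnd) {
  const int p = X.ncol();
  const int T = trees.size();
  NumericVector score(p);
  std::vector<double> base_pred;
  std::vector<int> perm;

  for (int t = 0; t < T; ++t) {
    TreeView tv(trees[t]);
    IntegerVector rows1 = idx_list[t];
    const int n = rows1.size();
    std::vector<int> rows(n);
    double W = 0.0;
    for (int i = 0; i < n; ++i) {
      rows[i] = rows1[i] - 1;
      W += w[rows[i]];
    }
    base_pred.assign(n, 0.0);
    double mse0 = 0.0;
    for (int i = 0; i < n; ++i) {
      base_pred[i] = tv.predict_row(X, rows[i], -1, 0.0);
      const double e = base_pred[i] - y[rows[i]];
      mse0 += w[rows[i]] * e * e;
    }
    mse0 /= W;

    for (int r = 0; r < n_rnd; ++r) {
      for (int f = 0; f < p; ++f) {
        // permutation of eval positions via Fisher-Yates on R's RNG
        perm.resize(n);
        for (int i = 0; i < n; ++i) perm[i] = i;
        for (int i = n - 1; i > 0; --i) {
          int j = (int)std::floor(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(perm[i], perm[j]);
        }
        double mse = 0.0;
        for (int i = 0; i < n; ++i) {
          const double xv = X(rows[perm[i]], f);
          const double pr = tv.predict_row(X, rows[i], f, xv);
          const double e = pr - y[rows[i]];
          mse += w[rows[i]] * e * e;
        }
        mse /= W;
        score[f] += (mse - mse0);
      }
    }
  }
  const double denom = (double)T * (double)n_rnd;
  for (int f = 0; f < p; ++f) score[f] /= denom;
  return score;
}
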