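// Classification-tree ensemble (CART, Gini) used by the window classifier.
// Implemented here because the runtime R library provides no tree package.
// Supports bagged forests with per-split feature subsampling (random forest),
// randomized-threshold splits without bagging (extra trees), and a single
// exhaustive tree (decision tree). Trees are returned as plain R vectors so
// fitted models serialize with saveRDS and predict identically after reload.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

// xorshift64* PRNG: deterministic across platforms/compilers, unlike
// std::uniform_int_distribution.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // integer in [0, n)
  uint64_t bounded(uint64_t n) { return next() % n; }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += c * c;
  return 1.0 - s / (n * n);
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, mtry, min_split, min_leaf, max_depth;
  bool random_splits;
  Rng rng;
  double n_total;

  std::vector<int> feature;     // -1 => leaf (then `left` is leaf row index)
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<std::vector<double>> leaf_probs;
  std::vector<double> importance; // raw impurity decrease, weighted by node share

  std::vector<int> idx;          // row indices, partitioned in place per node
  std::vector<int> feat_pool;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K_,
              int mtry_, int min_split_, int min_leaf_, int max_depth_,
              bool random_splits_, uint64_t seed,
              const std::vector<int>& rows)
    : X(X_), y(y_), K(K_), mtry(mtry_), min_split(min_split_),
      min_leaf(min_leaf_), max_depth(max_depth_),
      random_splits(random_splits_), rng(seed),
      n_total((double)rows.size()), idx(rows),
      feat_pool(X_.ncol()) {
    importance.assign(X.ncol(), 0.0);
    for (int j = 0; j < (int)feat_pool.size(); ++j) feat_pool[j] = j;
  }

  int make_leaf(const std::vector<double>& cnt, double n) {
    std::vector<double> p(K);
    for (int k = 0; k < K; ++k) p[k] = cnt[k] / n;
    leaf_probs.push_back(p);
    int node = (int)feature.size();
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back((int)leaf_probs.size() - 1);
    right.push_back(-1);
    return node;
  }

  // Find best split for rows idx[lo, hi); returns false if no usable split.
  bool find_split(int lo, int hi, const std::vector<double>& cnt, double node_imp,
                  int& best_f, double& best_thr, double& best_gain) {
    int n = hi - lo;
    best_f = -1; best_gain = 0.0;
    int p = (int)feat_pool.size();
    int ntry = std::min(mtry, p);
    std::vector<std::pair<double,int>> buf;
    std::vector<double> lc(K);
    // Draw features in random order until `ntry` non-constant candidates have
    // been evaluated (constant-at-node features do not count toward mtry, as
    // in the usual forest implementations); stop early only when the pool is
    // exhausted.
    int evaluated = 0;
    for (int t = 0; t < p && evaluated < ntry; ++t) {
      int j = t + (int)rng.bounded((uint64_t)(p - t));
      std::swap(feat_pool[t], feat_pool[j]);
      int f = feat_pool[t];
      if (random_splits) {
        double mn = R_PosInf, mx = R_NegInf;
        for (int i = lo; i < hi; ++i) {
          double v = X(idx[i], f);
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
        if (!(mx > mn)) continue;
        ++evaluated;
        double thr = mn + rng.unif() * (mx - mn);
        if (thr >= mx) thr = std::nextafter(mx, mn); // keep split non-empty
        std::fill(lc.begin(), lc.end(), 0.0);
        int nl = 0;
        for (int i = lo; i < hi; ++i) {
          if (X(idx[i], f) <= thr) { lc[y[idx[i]]] += 1.0; ++nl; }
        }
        int nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        std::vector<double> rc(K);
        for (int k = 0; k < K; ++k) rc[k] = cnt[k] - lc[k];
        double gain = node_imp
          - ((double)nl / n) * gini_from_counts(lc, nl)
          - ((double)nr / n) * gini_from_counts(rc, nr);
        if (gain > best_gain + 1e-12) { best_gain = gain; best_f = f; best_thr = thr; }
      } else {
        buf.clear();
        buf.reserve(n);
        for (int i = lo; i < hi; ++i) buf.emplace_back(X(idx[i], f), y[idx[i]]);
        std::sort(buf.begin(), buf.end());
        if (buf.front().first == buf.back().first) continue;
        ++evaluated;
        std::fill(lc.begin(), lc.end(), 0.0);
        double sl = 0.0, sr = 0.0; // running sum of squared counts
        std::vector<double> rc(cnt);
        for (int k = 0; k < K; ++k) sr += rc[k] * rc[k];
        for (int i = 0; i < n - 1; ++i) {
          int k = buf[i].second;
          sl += 2.0 * lc[k] + 1.0; lc[k] += 1.0;
          sr -= 2.0 * rc[k] - 1.0; rc[k] -= 1.0;
          if (buf[i].first == buf[i + 1].first) continue;
          int nl = i + 1, nr = n - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          double gain = node_imp
            - ((double)nl / n) * (1.0 - sl / ((double)nl * nl))
            - ((double)nr / n) * (1.0 - sr / ((double)nr * nr));
          if (gain > best_gain + 1e-12) {
            best_gain = gain; best_f = f;
            best_thr = buf[i].first + 0.5 * (buf[i + 1].first - buf[i].first);
            if (!(best_thr > buf[i].first)) best_thr = buf[i].first; // fp underflow
          }
        }
      }
    }
    return best_f >= 0;
  }

  int build(int lo, int hi, int depth) {
    int n = hi - lo;
    std::vector<double> cnt(K, 0.0);
    for (int i = lo; i < hi; ++i) cnt[y[idx[i]]] += 1.0;
    double node_imp = gini_from_counts(cnt, n);
    bool stop = n < min_split || node_imp <= 0.0 ||
      (max_depth > 0 && depth >= max_depth);
    int best_f = -1; double best_thr = 0.0, best_gain = 0.0;
    if (!stop) stop = !find_split(lo, hi, cnt, node_imp, best_f, best_thr, best_gain);
    if (stop) return make_leaf(cnt, n);

    importance[best_f] += ((double)n / n_total) * best_gain;
    int mid = lo;
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    // guard: degenerate partition (should not happen given find_split checks)
    if (mid == lo || mid == hi) return make_leaf(cnt, n);

    int node = (int)feature.size();
    feature.push_back(best_f);
    threshold.push_back(best_thr);
    left.push_back(-2);
    right.push_back(-2);
    int l = build(lo, mid, depth + 1);
    int r = build(mid, hi, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int n_classes,
                     int n_trees, int mtry, int min_split, int min_leaf,
                     int max_depth, bool bootstrap, bool random_splits,
                     double seed) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X and y disagree on the number of rows");
  List trees(n_trees);
  NumericVector imp(p);
  uint64_t base = (uint64_t)seed;
  for (int t = 0; t < n_trees; ++t) {
    Rng boot_rng(base * 0x9E3779B97F4A7C15ULL + 1000003ULL * (uint64_t)(t + 1));
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) rows[i] = (int)boot_rng.bounded((uint64_t)n);
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    TreeBuilder tb(X, y, n_classes, mtry, min_split, min_leaf, max_depth,
                   random_splits, boot_rng.next(), rows);
    int root = tb.build(0, n, 0);
    if (root != 0) stop("internal error: tree root is not node 0");
    int n_leaves = (int)tb.leaf_probs.size();
    NumericMatrix lp(n_leaves, n_classes);
    for (int i = 0; i < n_leaves; ++i)
      for (int k = 0; k < n_classes; ++k) lp(i, k) = tb.leaf_probs[i][k];
    trees[t] = List::create(
      _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
      _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["leaf_probs"] = lp);
    // per-tree normalized importance, averaged across trees (MDI convention)
    double tot = 0.0;
    for (int j = 0; j < p; ++j) tot += tb.importance[j];
    if (tot > 0) for (int j = 0; j < p; ++j) imp[j] += tb.importance[j] / tot;
  }
  for (int j = 0; j < p; ++j) imp[j] /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_forest(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, n_classes);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericMatrix lp = tr["leaf_probs"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      }
      int leaf = left[node];
      for (int k = 0; k < n_classes; ++k) out(i, k) += lp(leaf, k);
    }
  }
  if (T > 0) for (int i = 0; i < n; ++i)
    for (int k = 0; k < n_classes; ++k) out(i, k) /= T;
  return out;
}
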