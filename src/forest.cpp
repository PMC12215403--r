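// CART growing and prediction for the in-package random forest.
// All randomness (per-node feature subsampling) comes from R's RNG so a
// single set.seed() on the R side makes training bit-reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;  // 0/1
  int max_depth;           // -1 = unlimited
  int mtry;
  // flat node arrays (grow order); child index 0 = leaf sentinel
  std::vector<int> feature, left, right, nsamp, n0, n1;
  std::vector<double> threshold, impurity, value;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int max_depth_,
          int mtry_)
      : X(X_), y(y_), max_depth(max_depth_), mtry(mtry_) {}

  static double gini(int c0, int c1) {
    double n = c0 + c1;
    double p0 = c0 / n, p1 = c1 / n;
    return 1.0 - p0 * p0 - p1 * p1;
  }

  // partial Fisher-Yates draw of mtry features, then sorted ascending so the
  // first-strictly-better rule yields the lowest-index / lowest-threshold
  // winner among ties
  void sample_features(std::vector<int>& feats) {
    int p = X.ncol();
    std::vector<int> pool(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    int m = std::min(mtry, p);
    feats.resize(m);
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      if (j >= p) j = p - 1;
      std::swap(pool[i], pool[j]);
      feats[i] = pool[i];
    }
    std::sort(feats.begin(), feats.end());
  }

  // returns node index (1-based)
  int grow(std::vector<int>& idx, int depth) {
    int c0 = 0, c1 = 0;
    for (int i : idx) (y[i] == 0) ? ++c0 : ++c1;
    int node = (int)feature.size();
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    left.push_back(0);
    right.push_back(0);
    nsamp.push_back((int)idx.size());
    n0.push_back(c0);
    n1.push_back(c1);
    double imp = gini(c0, c1);
    impurity.push_back(imp);
    value.push_back((double)c1 / (c0 + c1));

    bool stop = (c0 == 0 || c1 == 0) ||
                (max_depth >= 0 && depth >= max_depth) || idx.size() < 2;
    if (!stop) {
      std::vector<int> feats;
      sample_features(feats);
      double best_gain = 1e-12;
      int best_f = -1;
      double best_t = 0.0;
      int n = (int)idx.size();
      std::vector<std::pair<double, int>> vals(n);
      for (int f : feats) {
        for (int i = 0; i < n; ++i)
          vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
        std::sort(vals.begin(), vals.end());
        if (vals.front().first == vals.back().first) continue;
        int l0 = 0, l1 = 0;
        for (int i = 0; i < n - 1; ++i) {
          (vals[i].second == 0) ? ++l0 : ++l1;
          if (vals[i].first == vals[i + 1].first) continue;
          int r0 = c0 - l0, r1 = c1 - l1;
          int nl = l0 + l1, nr = r0 + r1;
          double gain = imp - ((double)nl / n) * gini(l0, l1) -
                        ((double)nr / n) * gini(r0, r1);
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_t = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
          }
        }
      }
      if (best_f >= 0) {
        std::vector<int> lidx, ridx;
        lidx.reserve(idx.size());
        ridx.reserve(idx.size());
        for (int i : idx)
          (X(i, best_f) <= best_t) ? lidx.push_back(i) : ridx.push_back(i);
        feature[node] = best_f;
        threshold[node] = best_t;
        // children must be grown left-first for a reproducible layout
        int lchild = grow(lidx, depth + 1);
        int rchild = grow(ridx, depth + 1);
        left[node] = lchild;
        right[node] = rchild;
      }
    }
    return node + 1;  // 1-based
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, IntegerVector sample_idx,
                   int max_depth, int mtry) {
  RNGScope scope;
  Builder b(X, y, max_depth, mtry);
  std::vector<int> idx(sample_idx.size());
  for (int i = 0; i < sample_idx.size(); ++i) idx[i] = sample_idx[i] - 1;
  b.grow(idx, 0);
  return List::create(
      _["feature"] = wrap(b.feature), _["threshold"] = wrap(b.threshold),
      _["left"] = wrap(b.left), _["right"] = wrap(b.right),
      _["n_samples"] = wrap(b.nsamp), _["n0"] = wrap(b.n0),
      _["n1"] = wrap(b.n1), _["impurity"] = wrap(b.impurity),
      _["value"] = wrap(b.value));
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] - 1
                                                      : right[node] - 1;
    }
    out[i] = value[node];
  }
  return out;
}
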