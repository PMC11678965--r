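// Minimal CART random forest for binary classification.
//
// Gini-split trees on bootstrap samples with per-node feature subsampling,
// impurity-based importance, out-of-bag vote fractions and test-set vote
// fractions. Randomness comes from R's RNG stream (unif_rand), so results
// are reproducible under set.seed() on any platform.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat, left, right;
  std::vector<double> thr, pred; // pred = P(class 1) in leaf
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node, max_depth;
  std::vector<double>& importance;
  int n_inbag;
  Tree tree;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int min_node_, int max_depth_, std::vector<double>& imp_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
        importance(imp_), n_inbag(0) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  static double gini(int n1, int n) {
    if (n == 0) return 0.0;
    double p = double(n1) / n;
    return 2.0 * p * (1.0 - p);
  }

  int grow(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int node = (int)tree.feat.size();
    tree.feat.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(n > 0 ? double(n1) / n : 0.5);
    if (n1 == 0 || n1 == n || n < 2 * min_node || n < 2 ||
        depth >= max_depth)
      return node;

    double imp_parent = gini(n1, n);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    // sample mtry features without replacement (partial Fisher-Yates)
    int p = (int)feat_pool.size();
    for (int j = 0; j < mtry && j < p; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(feat_pool[j], feat_pool[r]);
    }

    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < std::min(mtry, p); ++j) {
      int f = feat_pool[j];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i + 1].first <= vals[i].first) continue; // tied values
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double g = imp_parent -
            (nl * gini(l1, nl) + nr * gini(n1 - l1, nr)) / n;
        if (g > best_gain) {
          best_gain = g;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;

    importance[best_f] += best_gain * n / n_inbag;
    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? lidx : ridx).push_back(i);
    tree.feat[node] = best_f;
    tree.thr[node] = best_thr;
    tree.left[node] = grow(lidx, depth + 1);
    tree.right[node] = grow(ridx, depth + 1);
    return node;
  }

  double predict_row(const NumericMatrix& M, int i) const {
    int node = 0;
    while (tree.feat[node] >= 0)
      node = (M(i, tree.feat[node]) <= tree.thr[node]) ? tree.left[node]
                                                       : tree.right[node];
    return tree.pred[node];
  }
};

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
                int ntree, int mtry, int min_node, int max_depth) {
  int n = X.nrow(), ntest = Xtest.nrow(), p = X.ncol();
  if (n < 2) stop("rf_fit_cpp: need at least 2 training rows");
  std::vector<double> importance(p, 0.0);
  std::vector<double> oob_votes1(n, 0.0);
  std::vector<int> oob_count(n, 0);
  std::vector<double> test_votes1(ntest, 0.0);
  std::vector<int> inbag(n);
  std::vector<int> idx;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    idx.reserve(n);
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      inbag[r]++;
      idx.push_back(r);
    }
    Builder b(X, y, mtry, min_node, max_depth, importance);
    b.n_inbag = n;
    b.grow(idx, 0);
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        oob_count[i]++;
        if (b.predict_row(X, i) > 0.5) oob_votes1[i] += 1.0;
      }
    }
    for (int i = 0; i < ntest; ++i)
      if (b.predict_row(Xtest, i) > 0.5) test_votes1[i] += 1.0;
  }

  NumericVector oob_prob(n);
  for (int i = 0; i < n; ++i)
    oob_prob[i] = oob_count[i] > 0 ? oob_votes1[i] / oob_count[i] : NA_REAL;
  NumericVector test_prob(ntest);
  for (int i = 0; i < ntest; ++i) test_prob[i] = test_votes1[i] / ntree;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;

  return List::create(_["importance"] = imp, _["oob_prob"] = oob_prob,
                      _["test_prob"] = test_prob);
}
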