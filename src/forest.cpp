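// Small CART random forest for binary classification: Gini splits,
// bootstrap bagging, mean-decrease-in-impurity importance, out-of-bag
// class-1 scores. Sized for radiomics-style problems (tens of samples,
// tens to hundreds of features). Uses R's RNG so results are governed by
// set.seed() on the R side.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // child indices
  double prob;     // class-1 fraction in node
};

struct Tree {
  std::vector<Node> nodes;
};

static double gini(double n1, double n) {
  if (n <= 0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

static int grow(const NumericMatrix& X, const IntegerVector& y,
                std::vector<int>& idx, int lo, int hi, int mtry,
                int min_node, Tree& tree, std::vector<double>& importance,
                int n_total) {
  int n = hi - lo;
  double n1 = 0;
  for (int t = lo; t < hi; ++t) n1 += y[idx[t]];
  int me = (int)tree.nodes.size();
  tree.nodes.push_back({-1, 0.0, -1, -1, n1 / n});
  double g_parent = gini(n1, n);
  if (n < 2 * min_node || n1 == 0 || n1 == n || g_parent <= 0) return me;

  int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  int m = std::min(mtry, p);
  for (int f = 0; f < m; ++f) {
    int pick = f + (int)(unif_rand() * (p - f));
    if (pick >= p) pick = p - 1;
    std::swap(feats[f], feats[pick]);
  }

  double best_dec = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int fi = 0; fi < m; ++fi) {
    int f = feats[fi];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double l1 = 0;
    for (int t = 0; t < n - 1; ++t) {
      l1 += y[ord[t]];
      if (X(ord[t], f) == X(ord[t + 1], f)) continue;
      double nl = t + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double dec = g_parent - (nl * gini(l1, nl) + nr * gini(n1 - l1, nr)) / n;
      if (dec > best_dec) {
        best_dec = dec;
        best_f = f;
        best_thr = 0.5 * (X(ord[t], f) + X(ord[t + 1], f));
      }
    }
  }
  if (best_f < 0) return me;

  importance[best_f] += best_dec * n / n_total;
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_f) <= best_thr) std::swap(idx[t], idx[mid++]);
  tree.nodes[me].feature = best_f;
  tree.nodes[me].threshold = best_thr;
  int l = grow(X, y, idx, lo, mid, mtry, min_node, tree, importance, n_total);
  int r = grow(X, y, idx, mid, hi, mtry, min_node, tree, importance, n_total);
  tree.nodes[me].left = l;
  tree.nodes[me].right = r;
  return me;
}

static double predict_one(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0)
    cur = (X(row, tree.nodes[cur].feature) <= tree.nodes[cur].threshold)
              ? tree.nodes[cur].left
              : tree.nodes[cur].right;
  return tree.nodes[cur].prob;
}

static NumericMatrix pack_tree(const Tree& tree) {
  NumericMatrix m(tree.nodes.size(), 5);
  for (size_t i = 0; i < tree.nodes.size(); ++i) {
    m(i, 0) = tree.nodes[i].feature;
    m(i, 1) = tree.nodes[i].threshold;
    m(i, 2) = tree.nodes[i].left;
    m(i, 3) = tree.nodes[i].right;
    m(i, 4) = tree.nodes[i].prob;
  }
  return m;
}

static Tree unpack_tree(const NumericMatrix& m) {
  Tree t;
  t.nodes.resize(m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    t.nodes[i] = {(int)m(i, 0), m(i, 1), (int)m(i, 2), (int)m(i, 3), m(i, 4)};
  return t;
}

// [[Rcpp::export(rng = true)]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_node) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_cnt(n, 0);
  List trees(n_trees);
  std::vector<int> idx;
  std::vector<char> inbag(n);
  for (int b = 0; b < n_trees; ++b) {
    idx.clear();
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int t = 0; t < n; ++t) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx.push_back(pick);
      inbag[pick] = 1;
    }
    Tree tree;
    grow(X, y, idx, 0, n, mtry, min_node, tree, importance, n);
    for (int t = 0; t < n; ++t)
      if (!inbag[t]) {
        oob_sum[t] += predict_one(tree, X, t);
        oob_cnt[t] += 1;
      }
    trees[b] = pack_tree(tree);
  }
  NumericVector imp(p);
  for (int f = 0; f < p; ++f) imp[f] = importance[f] / n_trees;
  NumericVector oob(n, NA_REAL);
  for (int t = 0; t < n; ++t)
    if (oob_cnt[t] > 0) oob[t] = oob_sum[t] / oob_cnt[t];
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["oob_scores"] = oob);
}

// [[Rcpp::export(rng = false)]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    Tree t = unpack_tree(as<NumericMatrix>(trees[b]));
    for (int i = 0; i < n; ++i) out[i] += predict_one(t, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
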