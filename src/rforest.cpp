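// Minimal random forest classifier (bagged CART, gini splitting, per-node
// feature subsampling). Written in-package because no random-forest library is
// available in the target environment. Uses R's RNG for reproducibility.
//
// Forest serialization: a list of numeric matrices, one per tree, with columns
//   0 feature (-1 => leaf), 1 threshold, 2 left child, 3 right child,
//   4..(4+K-1) leaf class proportions (NA for internal nodes).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Node {
  int feature = -1;
  double threshold = 0.0;
  int left = -1, right = -1;
  std::vector<double> prop;
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, mtry, min_node;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int K_, int mtry_, int min_node_)
      : X(X_), y(y_), K(K_), mtry(mtry_), min_node(min_node_) {}

  int make_leaf(const std::vector<int>& idx) {
    Node nd;
    nd.prop.assign(K, 0.0);
    for (int i : idx) nd.prop[y[i]] += 1.0;
    for (int k = 0; k < K; k++) nd.prop[k] /= (double)idx.size();
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }

  int build(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    bool pure = true;
    for (int i = 1; i < n; i++) if (y[idx[i]] != y[idx[0]]) { pure = false; break; }
    if (pure || n < 2 * min_node || depth > 30) return make_leaf(idx);

    int p = X.ncol();
    // sample mtry distinct features
    std::vector<int> feats(p);
    for (int j = 0; j < p; j++) feats[j] = j;
    for (int j = 0; j < mtry && j < p; j++) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(feats[j], feats[r]);
    }

    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    std::vector<double> tot(K, 0.0);
    for (int i : idx) tot[y[i]] += 1.0;
    double gini_all = 1.0;
    for (int k = 0; k < K; k++) gini_all -= (tot[k] / n) * (tot[k] / n);

    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < mtry && j < p; j++) {
      int f = feats[j];
      for (int i = 0; i < n; i++) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      std::vector<double> lc(K, 0.0);
      double nl = 0;
      for (int i = 0; i < n - 1; i++) {
        lc[vals[i].second] += 1.0;
        nl += 1.0;
        if (vals[i].first == vals[i + 1].first) continue;
        double nr = n - nl;
        double gl = 1.0, gr = 1.0;
        for (int k = 0; k < K; k++) {
          double pl = lc[k] / nl, pr = (tot[k] - lc[k]) / nr;
          gl -= pl * pl;
          gr -= pr * pr;
        }
        double gain = gini_all - (nl / n) * gl - (nr / n) * gr;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return make_leaf(idx);

    std::vector<int> li, ri;
    for (int i : idx) (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return make_leaf(idx);

    Node nd;
    nd.feature = best_feat;
    nd.threshold = best_thr;
    nodes.push_back(nd);
    int self = (int)nodes.size() - 1;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  NumericMatrix serialize() const {
    int n = (int)nodes.size();
    NumericMatrix m(n, 4 + K);
    for (int i = 0; i < n; i++) {
      m(i, 0) = nodes[i].feature;
      m(i, 1) = nodes[i].threshold;
      m(i, 2) = nodes[i].left;
      m(i, 3) = nodes[i].right;
      for (int k = 0; k < K; k++)
        m(i, 4 + k) = nodes[i].feature < 0 ? nodes[i].prop[k] : NA_REAL;
    }
    return m;
  }
};

static const double* tree_leaf(const NumericMatrix& tree, const NumericMatrix& X, int row,
                               std::vector<double>& buf, int K) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = X(row, f) <= tree(node, 1) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  for (int k = 0; k < K; k++) buf[k] = tree(node, 4 + k);
  return buf.data();
}

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, IntegerVector y, int K, int ntree, int mtry, int min_node) {
  int n = X.nrow();
  if (y.size() != n) stop("X and y size mismatch");
  for (int i = 0; i < n; i++)
    if (y[i] < 0 || y[i] >= K) stop("class labels must be in [0, K)");
  RNGScope scope;
  List trees(ntree);
  NumericMatrix oob_votes(n, K);
  IntegerVector oob_n(n, 0);
  std::vector<double> buf(K);
  for (int t = 0; t < ntree; t++) {
    std::vector<int> boot(n);
    std::vector<bool> inbag(n, false);
    for (int i = 0; i < n; i++) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      boot[i] = r;
      inbag[r] = true;
    }
    TreeBuilder tb(X, y, K, mtry, min_node);
    tb.build(boot, 0);
    NumericMatrix ser = tb.serialize();
    trees[t] = ser;
    for (int i = 0; i < n; i++) {
      if (inbag[i]) continue;
      const double* pr = tree_leaf(ser, X, i, buf, K);
      for (int k = 0; k < K; k++) oob_votes(i, k) += pr[k];
      oob_n[i]++;
    }
  }
  int correct = 0, assessed = 0;
  for (int i = 0; i < n; i++) {
    if (oob_n[i] == 0) continue;
    int arg = 0;
    for (int k = 1; k < K; k++) if (oob_votes(i, k) > oob_votes(i, arg)) arg = k;
    assessed++;
    if (arg == y[i]) correct++;
  }
  double oob_acc = assessed > 0 ? (double)correct / assessed : NA_REAL;
  return List::create(_["trees"] = trees, _["oob_accuracy"] = oob_acc);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericMatrix rf_predict(List trees, NumericMatrix X, int K) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, K);
  std::vector<double> buf(K);
  for (int t = 0; t < T; t++) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; i++) {
      const double* pr = tree_leaf(tree, X, i, buf, K);
      for (int k = 0; k < K; k++) out(i, k) += pr[k];
    }
  }
  for (int i = 0; i < n; i++)
    for (int k = 0; k < K; k++) out(i, k) /= (double)T;
  return out;
}
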