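// Compact random-forest classifier for binary (remission=0 / active=1) OTU
// classification: CART trees, Gini impurity, mtry features per node, bootstrap
// resampling, mean-decrease-in-impurity importance, and terminal-leaf export so
// proximities (fraction of trees in which two samples share a leaf) can be
// accumulated without retaining whole forests.
//
// Self-contained std::mt19937 RNG: forests are reproducible from an integer
// seed independently of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feat;  // -1 for a leaf
  std::vector<double> thr;
  std::vector<int> left, right, pred;
};

inline double gini_from_counts(int c1, int n) {
  if (n == 0) return 0.0;
  const double p1 = static_cast<double>(c1) / n;
  return 2.0 * p1 * (1.0 - p1);
}

class Grower {
public:
  Grower(const NumericMatrix& X, const IntegerVector& y, int mtry,
         int min_node, std::mt19937& rng, std::vector<double>& imp)
      : X_(X), y_(y), mtry_(mtry), min_node_(min_node), rng_(rng), imp_(imp),
        p_(X.ncol()), feat_pool_(X.ncol()) {
    for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
  }

  int grow(std::vector<int>& idx, TreeBuf& t, int n_boot) {
    const int n = static_cast<int>(idx.size());
    int c1 = 0;
    for (int i : idx) c1 += y_[i];
    const int node = new_node(t);
    if (c1 == 0 || c1 == n || n < 2 * min_node_) {
      make_leaf(t, node, c1, n);
      return node;
    }
    // draw mtry candidate features by partial Fisher-Yates
    int best_f = -1, best_nl = 0;
    double best_thr = 0.0, best_score = -1.0;
    const double parent_cost = static_cast<double>(n) * gini_from_counts(c1, n);
    for (int k = 0; k < mtry_; ++k) {
      std::uniform_int_distribution<int> pick(k, p_ - 1);
      std::swap(feat_pool_[k], feat_pool_[pick(rng_)]);
      const int f = feat_pool_[k];
      scan_feature(idx, f, c1, parent_cost, best_f, best_thr, best_nl, best_score);
    }
    if (best_f < 0) {  // no impurity-reducing split among candidates
      make_leaf(t, node, c1, n);
      return node;
    }
    imp_[best_f] += best_score / n_boot;
    std::vector<int> li, ri;
    li.reserve(best_nl);
    ri.reserve(n - best_nl);
    for (int i : idx)
      (X_(i, best_f) <= best_thr ? li : ri).push_back(i);
    t.feat[node] = best_f;
    t.thr[node] = best_thr;
    const int l = grow(li, t, n_boot);
    const int r = grow(ri, t, n_boot);
    t.left[node] = l;
    t.right[node] = r;
    return node;
  }

private:
  int new_node(TreeBuf& t) {
    t.feat.push_back(-1);
    t.thr.push_back(0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.pred.push_back(0);
    return static_cast<int>(t.feat.size()) - 1;
  }

  void make_leaf(TreeBuf& t, int node, int c1, int n) {
    t.feat[node] = -1;
    t.pred[node] = (2 * c1 > n) ? 1 : 0;  // tie -> remission (class 0)
  }

  void scan_feature(const std::vector<int>& idx, int f, int c1_tot,
                    double parent_cost, int& best_f, double& best_thr,
                    int& best_nl, double& best_score) {
    const int n = static_cast<int>(idx.size());
    order_.clear();
    order_.reserve(n);
    for (int i : idx) order_.emplace_back(X_(i, f), y_[i]);
    std::sort(order_.begin(), order_.end());
    if (order_.front().first == order_.back().first) return;  // constant
    int c1_left = 0;
    for (int k = 0; k < n - 1; ++k) {
      c1_left += order_[k].second;
      if (order_[k].first == order_[k + 1].first) continue;
      const int nl = k + 1, nr = n - nl;
      if (nl < min_node_ || nr < min_node_) continue;
      const double cost = nl * gini_from_counts(c1_left, nl) +
                          nr * gini_from_counts(c1_tot - c1_left, nr);
      const double score = parent_cost - cost;
      if (score > best_score + 1e-12) {
        best_score = score;
        best_f = f;
        best_thr = 0.5 * (order_[k].first + order_[k + 1].first);
        best_nl = nl;
      }
    }
  }

  const NumericMatrix& X_;
  const IntegerVector& y_;
  const int mtry_, min_node_;
  std::mt19937& rng_;
  std::vector<double>& imp_;
  const int p_;
  std::vector<int> feat_pool_;
  std::vector<std::pair<double, int>> order_;
};

int descend(const IntegerVector& feat, const NumericVector& thr,
            const IntegerVector& left, const IntegerVector& right,
            const NumericMatrix& X, int i) {
  int node = 0;
  while (feat[node] >= 0)
    node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
  return node;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_rf_fit")]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  for (int i = 0; i < n; ++i)
    if (y[i] != 0 && y[i] != 1) stop("y must be coded 0/1");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_int_distribution<int> boot(0, n - 1);
  std::vector<double> imp(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuf buf;
    Grower g(X, y, mtry, min_node, rng, imp);
    g.grow(idx, buf, n);
    trees[t] = List::create(_["feat"] = wrap(buf.feat), _["thr"] = wrap(buf.thr),
                            _["left"] = wrap(buf.left), _["right"] = wrap(buf.right),
                            _["pred"] = wrap(buf.pred));
  }
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = importance,
                      _["ntree"] = ntree, _["mtry"] = mtry);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_rf_votes")]]
NumericVector cpp_rf_votes(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int ntree = trees.size(), n = X.nrow();
  std::vector<int> active(n, 0);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"],
                  pred = tr["pred"];
    NumericVector thr = tr["thr"];
    for (int i = 0; i < n; ++i)
      active[i] += pred[descend(feat, thr, left, right, X, i)];
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = static_cast<double>(active[i]) / ntree;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_rf_leaves")]]
IntegerMatrix cpp_rf_leaves(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int ntree = trees.size(), n = X.nrow();
  IntegerMatrix leaves(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"];
    for (int i = 0; i < n; ++i)
      leaves(i, t) = descend(feat, thr, left, right, X, i);
  }
  return leaves;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_prox_accumulate")]]
void cpp_prox_accumulate(IntegerMatrix leaves, NumericMatrix acc) {
  // acc[i,j] += number of trees in which i and j share a terminal node;
  // modified in place so repeated models accumulate without copies.
  const int n = leaves.nrow(), ntree = leaves.ncol();
  if (acc.nrow() != n || acc.ncol() != n) stop("accumulator shape mismatch");
  std::vector<std::pair<int, int>> by_leaf(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) by_leaf[i] = {leaves(i, t), i};
    std::sort(by_leaf.begin(), by_leaf.end());
    int a = 0;
    while (a < n) {
      int b = a;
      while (b < n && by_leaf[b].first == by_leaf[a].first) ++b;
      for (int u = a; u < b; ++u)
        for (int v = u; v < b; ++v) {
          const int i = by_leaf[u].second, j = by_leaf[v].second;
          acc(i, j) += 1.0;
          if (i != j) acc(j, i) += 1.0;
        }
      a = b;
    }
  }
}
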