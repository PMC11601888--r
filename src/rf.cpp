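// Classification random forest: CART trees on bootstrap samples, Gini
// splitting over mtry randomly drawn candidate features, probability
// prediction as the across-tree mean of leaf class-1 fractions, and
// mean-decrease-Gini (MDG) variable importance. Self-seeded (std::mt19937)
// so fits and predictions are exactly reproducible given the seed.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int var;        // -1 for leaf
  double split;   // go left if x <= split
  int left, right;
  double prob;    // class-1 fraction (leaf)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node;
  std::mt19937 rng;
  std::vector<Node> nodes;
  std::vector<double>& imp;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_node_, unsigned seed, std::vector<double>& imp_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), rng(seed),
        imp(imp_) {}

  static double gini(double n1, double n) {
    if (n <= 0) return 0.0;
    double p = n1 / n;
    return 2.0 * p * (1.0 - p);
  }

  int build(std::vector<int>& idx) {
    int n = (int)idx.size();
    double n1 = 0;
    for (int i : idx) n1 += y[i];
    Node nd;
    nd.var = -1; nd.split = 0; nd.left = -1; nd.right = -1;
    nd.prob = n > 0 ? n1 / n : 0.5;
    double g_parent = gini(n1, n);
    if (n < std::max(2, min_node) || n1 == 0 || n1 == n) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    int p = X.ncol();
    // partial Fisher-Yates draw of mtry candidate features
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }
    double best_dec = 1e-12;
    int best_var = -1;
    double best_split = 0;
    std::vector<std::pair<double, int> > vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int j = feats[jj];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], j), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      double l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        double nl = i + 1, nr = n - nl;
        double dec = g_parent -
          (nl / n) * gini(l1, nl) - (nr / n) * gini(n1 - l1, nr);
        if (dec > best_dec) {
          best_dec = dec;
          best_var = j;
          best_split = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_var < 0) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_var) <= best_split ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) {  // numeric ties edge case
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    imp[best_var] += best_dec * n;  // node-size-weighted Gini decrease
    nd.var = best_var;
    nd.split = best_split;
    nodes.push_back(nd);
    int self = (int)nodes.size() - 1;
    int l = build(li);
    int r = build(ri);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

double predict_one(const NumericMatrix& tree, const NumericMatrix& X,
                   int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    node = X(row, (int)tree(node, 0)) <= tree(node, 1)
               ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export]]
List rf_grow_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                 int min_node, int seed) {
  int n = X.nrow(), p = X.ncol();
  if (n != y.size()) stop("X and y sizes differ");
  List trees(ntree);
  std::vector<double> imp(p, 0.0);
  for (int t = 0; t < ntree; ++t) {
    unsigned tree_seed = (unsigned)seed + 0x9E3779B9u * (unsigned)(t + 1);
    std::mt19937 boot_rng(tree_seed);
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(boot_rng);
    TreeBuilder tb(X, y, mtry, min_node, tree_seed ^ 0x5bd1e995u, imp);
    tb.nodes.reserve(2 * n);
    tb.build(idx);
    NumericMatrix tm((int)tb.nodes.size(), 5);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      tm(k, 0) = tb.nodes[k].var;
      tm(k, 1) = tb.nodes[k].split;
      tm(k, 2) = tb.nodes[k].left;
      tm(k, 3) = tb.nodes[k].right;
      tm(k, 4) = tb.nodes[k].prob;
    }
    trees[t] = tm;
  }
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tm, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
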