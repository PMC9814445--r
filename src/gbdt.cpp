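// Exact-greedy gradient-boosted decision trees for binary classification
// (Newton boosting on logistic loss), small-data oriented: dense features,
// no column/row subsampling, fully deterministic. Used as the layer-1
// learner of the stacked screening model.
//
// Split search presorts every feature once per fit; each node then scans
// the presorted order filtered by node membership (O(n) per feature per
// node), which keeps recursive feature elimination affordable.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <numeric>

using namespace Rcpp;

struct TreeNode {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // node indices
  double value;     // leaf value (already scaled by learning rate)
};

static double node_score(double G, double H, double lambda) {
  return (G * G) / (H + lambda);
}

static int build_node(const NumericMatrix &X,
                      const std::vector<std::vector<int>> &ord,
                      const std::vector<double> &g,
                      const std::vector<double> &h,
                      const std::vector<int> &idx,
                      std::vector<char> &member,
                      int depth, int max_depth,
                      double lambda, int min_leaf, double lr,
                      std::vector<TreeNode> &nodes,
                      std::vector<double> &importance) {
  double G = 0.0, H = 0.0;
  for (int i : idx) { G += g[i]; H += h[i]; }

  int me = (int)nodes.size();
  nodes.push_back(TreeNode{-1, 0.0, -1, -1, 0.0});

  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;

  if (depth < max_depth && (int)idx.size() >= 2 * min_leaf) {
    for (int i : idx) member[i] = 1;
    int p = X.ncol();
    int m = (int)idx.size();
    for (int f = 0; f < p; ++f) {
      double GL = 0.0, HL = 0.0;
      int seen = 0;
      double prev = 0.0;
      bool have_prev = false;
      double pend_gain = -1.0, pend_prev = 0.0;
      for (int i : ord[f]) {
        if (!member[i]) continue;
        double xv = X(i, f);
        if (have_prev && xv != prev && pend_gain >= 0.0) {
          // split between prev (left) and xv (right)
          if (pend_gain > best_gain) {
            best_gain = pend_gain;
            best_f = f;
            best_thr = 0.5 * (pend_prev + xv);
          }
        }
        GL += g[i]; HL += h[i]; ++seen;
        prev = xv; have_prev = true;
        if (seen >= min_leaf && m - seen >= min_leaf) {
          pend_gain = 0.5 * (node_score(GL, HL, lambda) +
                             node_score(G - GL, H - HL, lambda) -
                             node_score(G, H, lambda));
          pend_prev = xv;
        } else {
          pend_gain = -1.0;
        }
      }
    }
    for (int i : idx) member[i] = 0;
  }

  if (best_f < 0) {
    nodes[me].value = -lr * G / (H + lambda);
    return me;
  }

  std::vector<int> li, ri;
  li.reserve(idx.size()); ri.reserve(idx.size());
  for (int i : idx) {
    if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
  }
  importance[best_f] += best_gain;
  int l = build_node(X, ord, g, h, li, member, depth + 1, max_depth,
                     lambda, min_leaf, lr, nodes, importance);
  int r = build_node(X, ord, g, h, ri, member, depth + 1, max_depth,
                     lambda, min_leaf, lr, nodes, importance);
  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

static double predict_tree(const IntegerVector &feature,
                           const NumericVector &threshold,
                           const IntegerVector &left,
                           const IntegerVector &right,
                           const NumericVector &value,
                           const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
  }
  return value[node];
}

// [[Rcpp::export(name = ".gbdt_train_cpp")]]
List gbdt_train_cpp(NumericMatrix X, NumericVector y, int n_trees,
                    int max_depth, double learning_rate, double lambda,
                    int min_leaf) {
  int n = X.nrow(), p = X.ncol();
  if (n_trees < 1 || n < 2) stop("need at least 1 tree and 2 samples");

  // presorted sample order per feature (stable: ties keep row order)
  std::vector<std::vector<int>> ord(p);
  for (int f = 0; f < p; ++f) {
    ord[f].resize(n);
    std::iota(ord[f].begin(), ord[f].end(), 0);
    std::stable_sort(ord[f].begin(), ord[f].end(),
                     [&](int a, int b) { return X(a, f) < X(b, f); });
  }

  double ybar = std::accumulate(y.begin(), y.end(), 0.0) / n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double base = std::log(ybar / (1.0 - ybar));

  std::vector<double> F(n, base), g(n), h(n);
  std::vector<double> importance(p, 0.0);
  std::vector<char> member(n, 0);
  List trees(n_trees);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    std::vector<TreeNode> nodes;
    std::vector<int> idx(n);
    std::iota(idx.begin(), idx.end(), 0);
    build_node(X, ord, g, h, idx, member, 0, max_depth, lambda, min_leaf,
               learning_rate, nodes, importance);

    int m = (int)nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector threshold(m), value(m);
    for (int k = 0; k < m; ++k) {
      feature[k] = nodes[k].feature;
      threshold[k] = nodes[k].threshold;
      left[k] = nodes[k].left;
      right[k] = nodes[k].right;
      value[k] = nodes[k].value;
    }
    trees[t] = List::create(_["feature"] = feature,
                            _["threshold"] = threshold,
                            _["left"] = left, _["right"] = right,
                            _["value"] = value);

    for (int i = 0; i < n; ++i) {
      F[i] += predict_tree(feature, threshold, left, right, value, X, i);
    }
  }

  return List::create(_["trees"] = trees, _["base"] = base,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(name = ".gbdt_predict_cpp")]]
NumericVector gbdt_predict_cpp(List trees, double base, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int i = 0; i < n; ++i) {
      out[i] += predict_tree(feature, threshold, left, right, value, X, i);
    }
  }
  return out;
}
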