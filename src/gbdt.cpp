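// Deterministic Newton-boosting gradient-boosted decision trees.
// Exact greedy split search, L2-regularised leaf weights, squared-error
// regression and softmax multiclass objectives.  No stochastic subsampling:
// identical inputs always give identical models (ties in split gain are
// broken by the lowest feature index, then the first threshold scanned).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for a leaf
  std::vector<double> threshold; // go left iff x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf weight (unscaled by learning rate)
};

struct BuildCtx {
  const double* X; // column-major n x p
  int n, p;
  const std::vector<double>* g;
  const std::vector<double>* h;
  double lambda, min_gain;
  int max_depth, min_leaf;
  std::vector<double>* imp_gain;
  std::vector<double>* imp_count;
};

int build_node(Tree& tree, BuildCtx& ctx, std::vector<int>& idx, int depth) {
  double G = 0.0, H = 0.0;
  for (int i : idx) { G += (*ctx.g)[i]; H += (*ctx.h)[i]; }

  const int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(-G / (H + ctx.lambda));

  if (depth >= ctx.max_depth || (int)idx.size() < 2 * ctx.min_leaf)
    return node;

  const double parent_score = G * G / (H + ctx.lambda);
  double best_gain = ctx.min_gain;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(idx.size());
  for (int j = 0; j < ctx.p; ++j) {
    const double* col = ctx.X + (size_t)j * ctx.n;
    for (size_t k = 0; k < idx.size(); ++k)
      vals[k] = std::make_pair(col[idx[k]], idx[k]);
    std::sort(vals.begin(), vals.end());
    double GL = 0.0, HL = 0.0;
    for (size_t k = 0; k + 1 < vals.size(); ++k) {
      GL += (*ctx.g)[vals[k].second];
      HL += (*ctx.h)[vals[k].second];
      if (vals[k].first == vals[k + 1].first) continue;
      const int nl = (int)k + 1, nr = (int)vals.size() - nl;
      if (nl < ctx.min_leaf || nr < ctx.min_leaf) continue;
      const double GR = G - GL, HR = H - HL;
      const double gain = 0.5 * (GL * GL / (HL + ctx.lambda) +
                                 GR * GR / (HR + ctx.lambda) - parent_score);
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }

  if (best_feat < 0) return node;

  std::vector<int> lidx, ridx;
  const double* col = ctx.X + (size_t)best_feat * ctx.n;
  for (int i : idx)
    (col[i] <= best_thr ? lidx : ridx).push_back(i);

  (*ctx.imp_gain)[best_feat] += best_gain;
  (*ctx.imp_count)[best_feat] += 1.0;

  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  tree.value[node] = 0.0;
  tree.left[node] = build_node(tree, ctx, lidx, depth + 1);
  tree.right[node] = build_node(tree, ctx, ridx, depth + 1);
  return node;
}

double tree_predict_one(const Tree& t, const double* X, int n, int row) {
  int node = 0;
  while (t.feature[node] >= 0) {
    const double x = X[(size_t)t.feature[node] * n + row];
    node = (x <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

List tree_to_list(const Tree& t) {
  return List::create(_["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
                      _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
                      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
                      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
                      _["value"] = NumericVector(t.value.begin(), t.value.end()));
}

Tree tree_from_list(const List& l) {
  Tree t;
  IntegerVector f = l["feature"], le = l["left"], ri = l["right"];
  NumericVector th = l["threshold"], va = l["value"];
  t.feature.assign(f.begin(), f.end());
  t.threshold.assign(th.begin(), th.end());
  t.left.assign(le.begin(), le.end());
  t.right.assign(ri.begin(), ri.end());
  t.value.assign(va.begin(), va.end());
  return t;
}

} // namespace

// [[Rcpp::export(name = ".gbdt_train_cpp")]]
List gbdt_train_cpp(NumericMatrix X, NumericVector y, std::string objective,
                    int n_class, int n_rounds, double learning_rate,
                    int max_depth, int min_leaf, double lambda,
                    double min_gain) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> g(n), h(n);
  std::vector<double> imp_gain(p, 0.0), imp_count(p, 0.0);
  BuildCtx ctx{X.begin(), n, p, &g, &h, lambda, min_gain,
               max_depth, min_leaf, &imp_gain, &imp_count};

  List trees;
  double base = 0.0;

  if (objective == "regression") {
    for (int i = 0; i < n; ++i) base += y[i];
    base /= n;
    std::vector<double> pred(n, base);
    for (int r = 0; r < n_rounds; ++r) {
      for (int i = 0; i < n; ++i) { g[i] = pred[i] - y[i]; h[i] = 1.0; }
      Tree t;
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
      build_node(t, ctx, idx, 0);
      for (int i = 0; i < n; ++i)
        pred[i] += learning_rate * tree_predict_one(t, X.begin(), n, i);
      trees.push_back(tree_to_list(t));
    }
  } else if (objective == "multiclass") {
    const int K = n_class;
    std::vector<double> F((size_t)n * K, 0.0), prob((size_t)n * K);
    std::vector<Tree> built;
    for (int r = 0; r < n_rounds; ++r) {
      for (int i = 0; i < n; ++i) {
        double mx = F[i];
        for (int k = 1; k < K; ++k) mx = std::max(mx, F[(size_t)k * n + i]);
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          prob[(size_t)k * n + i] = std::exp(F[(size_t)k * n + i] - mx);
          s += prob[(size_t)k * n + i];
        }
        for (int k = 0; k < K; ++k) prob[(size_t)k * n + i] /= s;
      }
      for (int k = 0; k < K; ++k) {
        for (int i = 0; i < n; ++i) {
          const double pk = prob[(size_t)k * n + i];
          g[i] = pk - (((int)y[i]) == k ? 1.0 : 0.0);
          h[i] = std::max(pk * (1.0 - pk), 1e-16);
        }
        Tree t;
        std::vector<int> idx(n);
        for (int i = 0; i < n; ++i) idx[i] = i;
        build_node(t, ctx, idx, 0);
        for (int i = 0; i < n; ++i)
          F[(size_t)k * n + i] +=
              learning_rate * tree_predict_one(t, X.begin(), n, i);
        trees.push_back(tree_to_list(t));
      }
    }
  } else {
    stop("unknown objective: %s", objective.c_str());
  }

  return List::create(_["trees"] = trees, _["base"] = base,
                      _["objective"] = objective, _["n_class"] = n_class,
                      _["learning_rate"] = learning_rate,
                      _["importance_gain"] = NumericVector(imp_gain.begin(), imp_gain.end()),
                      _["importance_count"] = NumericVector(imp_count.begin(), imp_count.end()));
}

// [[Rcpp::export(name = ".gbdt_predict_cpp")]]
NumericMatrix gbdt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow();
  const std::string objective = as<std::string>(model["objective"]);
  const double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];

  if (objective == "regression") {
    const double base = as<double>(model["base"]);
    NumericMatrix out(n, 1);
    std::fill(out.begin(), out.end(), base);
    for (int r = 0; r < trees.size(); ++r) {
      Tree t = tree_from_list(trees[r]);
      for (int i = 0; i < n; ++i)
        out(i, 0) += lr * tree_predict_one(t, X.begin(), n, i);
    }
    return out;
  }

  const int K = as<int>(model["n_class"]);
  NumericMatrix out(n, K); // raw scores; softmax applied in R
  const int n_rounds = trees.size() / K;
  for (int r = 0; r < n_rounds; ++r) {
    for (int k = 0; k < K; ++k) {
      Tree t = tree_from_list(trees[r * K + k]);
      for (int i = 0; i < n; ++i)
        out(i, k) += lr * tree_predict_one(t, X.begin(), n, i);
    }
  }
  return out;
}
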