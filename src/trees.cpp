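// Regression-tree ensembles for LAI estimation: a single gradient-style
// tree builder (leaf = G/(H + lambda), gain = sum of GL^2/(HL+lambda) terms)
// serves both the random forest (lambda = 0, bootstrap rows, mtry feature
// subsampling -> CART with mean leaves) and the boosted ensemble
// (shrinkage, depth limit, L1/L2 leaf regularization).
//
// Randomness (bootstrap, mtry) comes from R's RNG so set.seed() in R makes
// every fit reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeBuilder {
  const double* X;  // column-major n x p
  int n, p;
  const std::vector<double>* g;  // targets (or residuals)
  int mtry, min_leaf, max_depth;
  double lambda, alpha;
  // node columns: var (-1 = leaf), split, left, right, value
  std::vector<double> var_, split_, left_, right_, value_;

  double leaf_value(double G, double H) const {
    double S = G;
    if (alpha > 0.0) {
      if (S > alpha) S -= alpha;
      else if (S < -alpha) S += alpha;
      else S = 0.0;
    }
    return S / (H + lambda);
  }

  int new_node() {
    var_.push_back(-1.0); split_.push_back(0.0);
    left_.push_back(-1.0); right_.push_back(-1.0); value_.push_back(0.0);
    return static_cast<int>(var_.size()) - 1;
  }

  int build(std::vector<int>& idx, int depth) {
    const int node = new_node();
    const int m = static_cast<int>(idx.size());
    double G = 0.0;
    for (int i : idx) G += (*g)[i];
    const double H = static_cast<double>(m);
    value_[node] = leaf_value(G, H);
    if (depth >= max_depth || m < 2 * min_leaf) return node;

    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    const int k = std::min(mtry, p);
    for (int j = 0; j < k; ++j) {
      int r = j + static_cast<int>(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(feats[j], feats[r]);
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    const double parent_score = G * G / (H + lambda);
    std::vector<std::pair<double, double>> xv(m);  // (x, g)
    for (int jj = 0; jj < k; ++jj) {
      const int f = feats[jj];
      const double* col = X + static_cast<size_t>(f) * n;
      for (int i = 0; i < m; ++i) xv[i] = {col[idx[i]], (*g)[idx[i]]};
      std::sort(xv.begin(), xv.end());
      if (xv.front().first == xv.back().first) continue;
      double GL = 0.0;
      for (int i = 1; i < m; ++i) {
        GL += xv[i - 1].second;
        if (xv[i].first <= xv[i - 1].first) continue;
        if (i < min_leaf || m - i < min_leaf) continue;
        const double HL = i, HR = m - i;
        const double GR = G - GL;
        const double gain =
            GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent_score;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xv[i - 1].first + xv[i].first);
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> li, ri;
    li.reserve(m); ri.reserve(m);
    const double* col = X + static_cast<size_t>(best_f) * n;
    for (int i : idx) {
      if (col[i] <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;  // ties at threshold
    var_[node] = best_f;
    split_[node] = best_thr;
    const int lc = build(li, depth + 1);
    const int rc = build(ri, depth + 1);
    left_[node] = lc;
    right_[node] = rc;
    return node;
  }

  NumericMatrix as_matrix() const {
    const int nn = static_cast<int>(var_.size());
    NumericMatrix M(nn, 5);
    for (int i = 0; i < nn; ++i) {
      M(i, 0) = var_[i]; M(i, 1) = split_[i];
      M(i, 2) = left_[i]; M(i, 3) = right_[i]; M(i, 4) = value_[i];
    }
    return M;
  }
};

double predict_one(const NumericMatrix& tree, const double* X, int n, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = static_cast<int>(tree(node, 0));
    const double x = X[static_cast<size_t>(f) * n + row];
    node = static_cast<int>(x <= tree(node, 1) ? tree(node, 2) : tree(node, 3));
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf(NumericMatrix X, NumericVector y, int ntree, int mtry,
            int min_leaf, int max_depth, double sample_frac,
            bool replace) {
  const int n = X.nrow();
  const int nboot = std::max(1, static_cast<int>(sample_frac * n + 0.5));
  std::vector<double> g(y.begin(), y.end());
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx;
    idx.reserve(nboot);
    if (replace) {
      for (int i = 0; i < nboot; ++i) {
        int r = static_cast<int>(unif_rand() * n);
        if (r >= n) r = n - 1;
        idx.push_back(r);
      }
    } else {
      std::vector<int> all(n);
      for (int i = 0; i < n; ++i) all[i] = i;
      for (int i = 0; i < nboot; ++i) {
        int r = i + static_cast<int>(unif_rand() * (n - i));
        if (r >= n) r = n - 1;
        std::swap(all[i], all[r]);
        idx.push_back(all[i]);
      }
    }
    TreeBuilder tb{REAL(X), n, X.ncol(), &g, mtry, min_leaf, max_depth,
                   0.0, 0.0, {}, {}, {}, {}, {}};
    tb.build(idx, 0);
    trees[t] = tb.as_matrix();
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, 0.0);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, REAL(X), n, i);
  }
  const double nt = static_cast<double>(trees.size());
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}

// [[Rcpp::export]]
List cpp_gbt(NumericMatrix X, NumericVector y, int nrounds,
             double learning_rate, int max_depth, int min_leaf,
             double lambda, double alpha) {
  const int n = X.nrow();
  const int p = X.ncol();
  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;
  std::vector<double> pred(n, base), resid(n);
  std::vector<int> all(n);
  List trees(nrounds);
  for (int t = 0; t < nrounds; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - pred[i];
    TreeBuilder tb{REAL(X), n, p, &resid, p, min_leaf, max_depth,
                   lambda, alpha, {}, {}, {}, {}, {}};
    for (int i = 0; i < n; ++i) all[i] = i;
    std::vector<int> idx(all);
    tb.build(idx, 0);
    NumericMatrix tree = tb.as_matrix();
    trees[t] = tree;
    for (int i = 0; i < n; ++i) {
      pred[i] += learning_rate * predict_one(tree, REAL(X), n, i);
    }
  }
  return List::create(_["trees"] = trees, _["base"] = base);
}

// [[Rcpp::export]]
NumericVector cpp_predict_gbt(List trees, double base, double learning_rate,
                              NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) {
      out[i] += learning_rate * predict_one(tree, REAL(X), n, i);
    }
  }
  return out;
}
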