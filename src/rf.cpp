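// Small regression random forest with impurity (variance-reduction)
// importances, used for lagged Granger-style regulator ranking.
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  std::vector<int> idx;
};

// best split of `idx` on feature `f`: returns SSE decrease and threshold
bool best_split(const NumericMatrix& X, const NumericVector& y,
                const std::vector<int>& idx, int f, double parent_sse,
                double& best_dec, double& best_thr) {
  const int n = idx.size();
  std::vector<std::pair<double, double>> v(n);  // (x, y)
  for (int i = 0; i < n; ++i) v[i] = {X(idx[i], f), y[idx[i]]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return false;
  double sum_r = 0.0, sumsq_r = 0.0;
  for (auto& p : v) { sum_r += p.second; sumsq_r += p.second * p.second; }
  double sum_l = 0.0, sumsq_l = 0.0;
  bool found = false;
  for (int i = 0; i < n - 1; ++i) {
    sum_l += v[i].second;  sumsq_l += v[i].second * v[i].second;
    sum_r -= v[i].second;  sumsq_r -= v[i].second * v[i].second;
    if (v[i].first == v[i + 1].first) continue;
    int nl = i + 1, nr = n - nl;
    double sse_l = sumsq_l - sum_l * sum_l / nl;
    double sse_r = sumsq_r - sum_r * sum_r / nr;
    double dec = parent_sse - sse_l - sse_r;
    if (!found || dec > best_dec) {
      best_dec = dec;
      best_thr = 0.5 * (v[i].first + v[i + 1].first);
      found = true;
    }
  }
  return found;
}

double node_sse(const NumericVector& y, const std::vector<int>& idx) {
  double s = 0.0, sq = 0.0;
  for (int i : idx) { s += y[i]; sq += y[i] * y[i]; }
  return sq - s * s / idx.size();
}

}  // namespace

// [[Rcpp::export]]
NumericVector rf_importance_cpp(NumericMatrix X, NumericVector y,
                                int n_trees, int mtry, int min_node) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  NumericVector imp(p);
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int tree = 0; tree < n_trees; ++tree) {
    // bootstrap sample
    Node root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i)
      root.idx[i] = static_cast<int>(unif_rand() * n);
    std::vector<Node> stack;
    stack.push_back(std::move(root));
    while (!stack.empty()) {
      Node node = std::move(stack.back());
      stack.pop_back();
      const int nn = node.idx.size();
      if (nn < 2 * min_node) continue;
      double sse = node_sse(y, node.idx);
      if (sse <= 1e-12) continue;
      // sample mtry features without replacement (partial Fisher-Yates)
      for (int j = 0; j < mtry; ++j) {
        int k = j + static_cast<int>(unif_rand() * (p - j));
        std::swap(feats[j], feats[k]);
      }
      double best_dec = 0.0, best_thr = 0.0;
      int best_f = -1;
      for (int j = 0; j < mtry; ++j) {
        double dec, thr;
        if (best_split(X, y, node.idx, feats[j], sse, dec, thr)) {
          if (best_f < 0 || dec > best_dec) {
            best_dec = dec; best_thr = thr; best_f = feats[j];
          }
        }
      }
      if (best_f < 0) continue;
      imp[best_f] += best_dec;
      Node left, right;
      for (int i : node.idx) {
        if (X(i, best_f) <= best_thr) left.idx.push_back(i);
        else right.idx.push_back(i);
      }
      if (left.idx.size() >= 1) stack.push_back(std::move(left));
      if (right.idx.size() >= 1) stack.push_back(std::move(right));
    }
  }
  for (int j = 0; j < p; ++j) imp[j] /= n_trees;
  return imp;
}
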