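// Regression random forest for one response (one SNP's population allele
// frequencies) that records, per split, the predictor, split value and
// impurity (SSE) improvement -- the raw material of gradient-forest turnover
// functions -- plus out-of-bag predictions and OOB permutation importance.
// Sample sizes here are tiny (tens of populations), so a compact recursive
// CART with bootstrap resampling is entirely adequate.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int var;        // -1 for leaf
  double thresh;
  int left, right;
  double pred;
};

struct SplitRec {
  int var;
  double value;
  double improvement;
};

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, min_split;
  std::vector<Node> nodes;
  std::vector<SplitRec>& splits;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
              int min_split_, std::vector<SplitRec>& splits_)
    : X(X_), y(y_), mtry(mtry_), min_split(min_split_), splits(splits_) {}

  int build(std::vector<int>& idx) {
    int node_id = (int)nodes.size();
    nodes.push_back(Node());
    double sum = 0.0, sumsq = 0.0;
    for (int i : idx) { sum += y[i]; sumsq += y[i] * y[i]; }
    int n = (int)idx.size();
    double ss_parent = sumsq - sum * sum / n;
    Node nd; nd.var = -1; nd.thresh = 0.0; nd.left = nd.right = -1;
    nd.pred = sum / n;
    if (n < min_split || ss_parent <= 1e-12) { nodes[node_id] = nd; return node_id; }

    // sample mtry predictors without replacement (R RNG for seedability)
    int p = X.ncol();
    std::vector<int> vars(p);
    for (int j = 0; j < p; ++j) vars[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(vars[j], vars[k]);
    }

    double best_imp = 0.0, best_thresh = 0.0;
    int best_var = -1;
    std::vector<int> ord(idx);
    for (int j = 0; j < mtry && j < p; ++j) {
      int v = vars[j];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, v) < X(b, v);
      });
      double lsum = 0.0, lsumsq = 0.0;
      for (int k = 0; k + 1 < n; ++k) {
        int i = ord[k];
        lsum += y[i]; lsumsq += y[i] * y[i];
        if (X(ord[k + 1], v) <= X(i, v) + 1e-12) continue;  // tied values
        int nl = k + 1, nr = n - nl;
        double rsum = sum - lsum, rsumsq = sumsq - lsumsq;
        double ss_l = lsumsq - lsum * lsum / nl;
        double ss_r = rsumsq - rsum * rsum / nr;
        double imp = ss_parent - ss_l - ss_r;
        if (imp > best_imp) {
          best_imp = imp;
          best_var = v;
          best_thresh = 0.5 * (X(i, v) + X(ord[k + 1], v));
        }
      }
    }
    if (best_var < 0) { nodes[node_id] = nd; return node_id; }

    SplitRec rec; rec.var = best_var; rec.value = best_thresh;
    rec.improvement = best_imp;
    splits.push_back(rec);

    std::vector<int> lidx, ridx;
    for (int i : idx)
      (X(i, best_var) <= best_thresh ? lidx : ridx).push_back(i);
    nd.var = best_var; nd.thresh = best_thresh;
    nodes[node_id] = nd;
    int l = build(lidx), r = build(ridx);
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }

  double predict_row(int root, const std::vector<double>& row) const {
    int cur = root;
    while (nodes[cur].var >= 0)
      cur = (row[nodes[cur].var] <= nodes[cur].thresh) ? nodes[cur].left
                                                       : nodes[cur].right;
    return nodes[cur].pred;
  }
};

}  // namespace

// [[Rcpp::export]]
List gf_forest_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                   int min_split) {
  int n = X.nrow(), p = X.ncol();
  RNGScope scope;

  NumericVector oob_sum(n), oob_cnt(n);
  NumericVector imp(p);          // summed OOB MSE increase per predictor
  NumericVector imp_trees(p);    // trees contributing per predictor
  std::vector<double> sp_var, sp_val, sp_imp;

  for (int t = 0; t < ntree; ++t) {
    // bootstrap
    std::vector<int> bag;
    std::vector<bool> inbag(n, false);
    bag.reserve(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      bag.push_back(k);
      inbag[k] = true;
    }
    std::vector<SplitRec> splits;
    TreeBuilder tb(X, y, mtry, min_split, splits);
    int root = tb.build(bag);
    for (const SplitRec& s : splits) {
      sp_var.push_back(s.var + 1);
      sp_val.push_back(s.value);
      sp_imp.push_back(s.improvement);
    }

    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    std::vector<double> row(p);
    double mse0 = 0.0;
    std::vector<double> pred0(oob.size());
    for (size_t k = 0; k < oob.size(); ++k) {
      int i = oob[k];
      for (int j = 0; j < p; ++j) row[j] = X(i, j);
      pred0[k] = tb.predict_row(root, row);
      oob_sum[i] += pred0[k];
      oob_cnt[i] += 1.0;
      mse0 += (pred0[k] - y[i]) * (pred0[k] - y[i]);
    }
    mse0 /= oob.size();

    // OOB permutation importance per predictor
    int m = (int)oob.size();
    std::vector<int> perm(m);
    for (int v = 0; v < p; ++v) {
      for (int k = 0; k < m; ++k) perm[k] = k;
      for (int k = 0; k < m; ++k) {
        int k2 = k + (int)(unif_rand() * (m - k));
        if (k2 >= m) k2 = m - 1;
        std::swap(perm[k], perm[k2]);
      }
      double mse1 = 0.0;
      for (int k = 0; k < m; ++k) {
        int i = oob[k];
        for (int j = 0; j < p; ++j) row[j] = X(i, j);
        row[v] = X(oob[perm[k]], v);
        double pr = tb.predict_row(root, row);
        mse1 += (pr - y[i]) * (pr - y[i]);
      }
      mse1 /= m;
      imp[v] += mse1 - mse0;
      imp_trees[v] += 1.0;
    }
  }

  NumericVector oob_pred(n);
  for (int i = 0; i < n; ++i)
    oob_pred[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  for (int v = 0; v < p; ++v)
    imp[v] = imp_trees[v] > 0 ? imp[v] / imp_trees[v] : 0.0;

  return List::create(
    _["oob_pred"] = oob_pred,
    _["importance"] = imp,
    _["split_var"] = wrap(sp_var),
    _["split_value"] = wrap(sp_val),
    _["split_improvement"] = wrap(sp_imp));
}
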