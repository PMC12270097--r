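// Small deterministic regression random forest with out-of-bag (OOB)
// evaluation and OOB permutation importance. CART splits minimising SSE,
// bootstrap resampling per tree, mtry features per node. The RNG is a
// self-contained mt19937 seeded from the caller so results are identical
// across platforms and independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.0; // go left if x <= threshold
  int left = -1, right = -1;
  double pred = 0.0;
};

struct Tree {
  std::vector<Node> nodes;

  double predict(const double *row, int /*p*/) const {
    int id = 0;
    while (nodes[id].feature >= 0) {
      id = (row[nodes[id].feature] <= nodes[id].threshold)
               ? nodes[id].left : nodes[id].right;
    }
    return nodes[id].pred;
  }
};

// Grow one CART regression tree on the bootstrap sample.
void grow(Tree &tree, const NumericMatrix &X, const NumericVector &y,
          std::vector<int> &idx, int mtry, int min_node, std::mt19937 &rng) {
  const int p = X.ncol();
  struct Work { int node; int lo, hi; };
  std::vector<Work> stack;

  tree.nodes.emplace_back();
  stack.push_back({0, 0, (int)idx.size()});
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;

  while (!stack.empty()) {
    Work w = stack.back(); stack.pop_back();
    const int n = w.hi - w.lo;
    double sum = 0.0, sum2 = 0.0;
    for (int k = w.lo; k < w.hi; ++k) { sum += y[idx[k]]; sum2 += y[idx[k]] * y[idx[k]]; }
    const double mean = sum / n;
    Node &nd0 = tree.nodes[w.node];
    nd0.pred = mean;
    const double node_sse = sum2 - sum * sum / n;
    if (n <= min_node || node_sse <= 1e-12) continue;

    // sample mtry candidate features without replacement
    std::shuffle(feats.begin(), feats.end(), rng);
    int best_f = -1; double best_thr = 0.0, best_gain = 1e-12;

    std::vector<int> local(idx.begin() + w.lo, idx.begin() + w.hi);
    for (int fi = 0; fi < mtry && fi < p; ++fi) {
      const int f = feats[fi];
      std::sort(local.begin(), local.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double lsum = 0.0;
      for (int k = 0; k + 1 < n; ++k) {
        lsum += y[local[k]];
        if (X(local[k], f) == X(local[k + 1], f)) continue;
        const int nl = k + 1, nr = n - nl;
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (X(local[k], f) + X(local[k + 1], f));
        }
      }
    }
    if (best_f < 0) continue;

    // partition idx[lo,hi) in place
    int mid = w.lo;
    for (int k = w.lo; k < w.hi; ++k) {
      if (X(idx[k], best_f) <= best_thr) std::swap(idx[k], idx[mid++]);
    }
    if (mid == w.lo || mid == w.hi) continue; // degenerate (shouldn't happen)

    const int li = (int)tree.nodes.size();
    tree.nodes.emplace_back();
    const int ri = (int)tree.nodes.size();
    tree.nodes.emplace_back();
    Node &nd = tree.nodes[w.node]; // re-take reference after growth
    nd.feature = best_f; nd.threshold = best_thr;
    nd.left = li; nd.right = ri;
    stack.push_back({li, w.lo, mid});
    stack.push_back({ri, mid, w.hi});
  }
}

} // namespace

// [[Rcpp::export(name = ".rf_regression")]]
List rf_regression(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                   int min_node, int seed, IntegerMatrix strata) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<double> imp(p, 0.0);
  int trees_with_oob = 0;

  std::mt19937 master(static_cast<uint32_t>(seed));
  std::vector<uint32_t> tree_seed(n_trees);
  for (int t = 0; t < n_trees; ++t) tree_seed[t] = master();

  std::vector<double> row(p);

  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng(tree_seed[t]);
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::vector<int> boot(n);
    std::vector<char> inbag(n, 0);
    for (int i = 0; i < n; ++i) { boot[i] = pick(rng); inbag[boot[i]] = 1; }

    Tree tree;
    grow(tree, X, y, boot, mtry, min_node, rng);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;
    ++trees_with_oob;

    const int m = (int)oob.size();
    std::vector<double> base_pred(m);
    double mse0 = 0.0;
    for (int k = 0; k < m; ++k) {
      const int i = oob[k];
      for (int j = 0; j < p; ++j) row[j] = X(i, j);
      base_pred[k] = tree.predict(row.data(), p);
      oob_sum[i] += base_pred[k];
      oob_cnt[i] += 1;
      const double e = base_pred[k] - y[i];
      mse0 += e * e;
    }
    mse0 /= m;

    // OOB permutation importance, optionally within strata
    std::vector<int> perm(m);
    for (int f = 0; f < p; ++f) {
      for (int k = 0; k < m; ++k) perm[k] = k;
      bool use_strata = strata.ncol() == p && strata.nrow() == n;
      if (use_strata) {
        // group oob positions by stratum id for this feature, shuffle within
        std::vector<std::pair<int,int>> keyed(m);
        for (int k = 0; k < m; ++k) keyed[k] = { strata(oob[k], f), k };
        std::stable_sort(keyed.begin(), keyed.end(),
                         [](const std::pair<int,int> &a, const std::pair<int,int> &b) {
                           return a.first < b.first;
                         });
        int s = 0;
        while (s < m) {
          int e2 = s;
          while (e2 < m && keyed[e2].first == keyed[s].first) ++e2;
          // shuffle the member positions of this stratum
          std::vector<int> members(e2 - s);
          for (int k = s; k < e2; ++k) members[k - s] = keyed[k].second;
          std::vector<int> shuffled = members;
          std::shuffle(shuffled.begin(), shuffled.end(), rng);
          for (size_t k = 0; k < members.size(); ++k)
            perm[members[k]] = shuffled[k];
          s = e2;
        }
      } else {
        std::shuffle(perm.begin(), perm.end(), rng);
      }
      double mse1 = 0.0;
      for (int k = 0; k < m; ++k) {
        const int i = oob[k];
        for (int j = 0; j < p; ++j) row[j] = X(i, j);
        row[f] = X(oob[perm[k]], f);
        const double e = tree.predict(row.data(), p) - y[i];
        mse1 += e * e;
      }
      mse1 /= m;
      imp[f] += (mse1 - mse0);
    }
  }

  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_cnt[i] > 0) oob_pred[i] = oob_sum[i] / oob_cnt[i];
  NumericVector importance(p);
  const int denom = trees_with_oob > 0 ? trees_with_oob : 1;
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / denom;

  return List::create(_["oob_pred"] = oob_pred,
                      _["importance"] = importance,
                      _["trees_with_oob"] = trees_with_oob);
}
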