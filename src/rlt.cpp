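// Reinforcement-learning-tree regression forest:
// embedded-importance split selection with progressive variable muting.
// All randomness flows through R's RNG (seeded from R with set.seed).
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Node {
  int var;      // 0-based split variable, -1 for leaf
  double split; // route left when x <= split
  int left, right; // 0-based node indices, -1 for leaf
  double pred;  // mean of training y in node
  int n;
};

static double node_mean(const NumericVector& y, const std::vector<int>& idx) {
  double s = 0.0;
  for (int i : idx) s += y[i];
  return s / idx.size();
}

static bool y_constant(const NumericVector& y, const std::vector<int>& idx) {
  double mn = y[idx[0]], mx = mn;
  for (int i : idx) { if (y[i] < mn) mn = y[i]; if (y[i] > mx) mx = y[i]; }
  return (mx - mn) < 1e-12;
}

// Best variance-reduction split of variable j over rows idx.
// gain = S_L^2/n_L + S_R^2/n_R - S^2/n  (SSE reduction; the y^2 term cancels).
// Both children must hold >= min_child rows. Ties in gain keep the first
// (lowest) cutpoint. Returns false when no admissible cutpoint exists.
static bool best_split_var(const NumericMatrix& X, const NumericVector& y,
                           const std::vector<int>& idx, int j, int min_child,
                           double& gain, double& cut) {
  const int m = (int)idx.size();
  if (m < 2 * min_child) return false;
  std::vector<std::pair<double, double>> v(m);
  for (int i = 0; i < m; ++i) v[i] = std::make_pair(X(idx[i], j), y[idx[i]]);
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return false;
  double S = 0.0;
  for (int i = 0; i < m; ++i) S += v[i].second;
  double SL = 0.0, best = -1.0, bestcut = 0.0;
  const double base = S * S / m;
  for (int i = 0; i < m - 1; ++i) {
    SL += v[i].second;
    int nl = i + 1, nr = m - nl;
    if (nl < min_child || nr < min_child) continue;
    if (v[i].first == v[i + 1].first) continue; // not a boundary between distinct values
    double g = SL * SL / nl + (S - SL) * (S - SL) / nr - base;
    if (g > best + 1e-12) { best = g; bestcut = 0.5 * (v[i].first + v[i + 1].first); }
  }
  if (best <= 0.0) return false;
  gain = best; cut = bestcut;
  return true;
}

// ---- small greedy trees for the embedded importance ensemble ----

static int fit_greedy_node(const NumericMatrix& X, const NumericVector& y,
                           const std::vector<int>& idx,
                           const std::vector<int>& feats, int min_child,
                           int depth, int max_depth, std::vector<Node>& nodes) {
  Node nd; nd.var = -1; nd.split = 0.0; nd.left = -1; nd.right = -1;
  nd.pred = node_mean(y, idx); nd.n = (int)idx.size();
  int me = (int)nodes.size();
  nodes.push_back(nd);
  if (depth >= max_depth || (int)idx.size() < 2 * min_child || y_constant(y, idx))
    return me;
  double bg = -1.0, bc = 0.0; int bj = -1;
  for (int j : feats) {
    double g, c;
    if (best_split_var(X, y, idx, j, min_child, g, c) && g > bg + 1e-12) {
      bg = g; bc = c; bj = j;
    }
  }
  if (bj < 0) return me;
  std::vector<int> li, ri;
  for (int i : idx) (X(i, bj) <= bc ? li : ri).push_back(i);
  nodes[me].var = bj; nodes[me].split = bc;
  int l = fit_greedy_node(X, y, li, feats, min_child, depth + 1, max_depth, nodes);
  int r = fit_greedy_node(X, y, ri, feats, min_child, depth + 1, max_depth, nodes);
  nodes[me].left = l; nodes[me].right = r;
  return me;
}

// Predict row `row`, optionally overriding column `ovr_var` with `ovr_val`.
static double predict_row(const std::vector<Node>& nodes, const NumericMatrix& X,
                          int row, int ovr_var, double ovr_val) {
  int k = 0;
  while (nodes[k].var >= 0) {
    double x = (nodes[k].var == ovr_var) ? ovr_val : X(row, nodes[k].var);
    k = (x <= nodes[k].split) ? nodes[k].left : nodes[k].right;
  }
  return nodes[k].pred;
}

static int runif_int(int n) { // uniform on {0, ..., n-1} via R's RNG
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// k distinct elements of pool, partial Fisher-Yates, R RNG
static std::vector<int> sample_without_replacement(std::vector<int> pool, int k) {
  int n = (int)pool.size();
  for (int i = 0; i < k; ++i) std::swap(pool[i], pool[i + runif_int(n - i)]);
  pool.resize(k);
  return pool;
}

// Embedded importance at one node. For embedded_trees == 1 this is the exact
// best-single-split variance reduction of each candidate on the full node
// data (which makes the muting-off / single-tree configuration coincide with
// a classical greedy CART). Otherwise it is out-of-bag permutation
// importance averaged over an ensemble of depth-limited greedy trees fit on
// node row-subsamples (all candidates offered): one level of lookahead, so a
// variable whose effect is conditional (e.g. a treatment indicator with
// strata-cancelling marginal effect) still registers positive importance.
// A candidate's importance is kept only when it is decisively nonzero --
// mean/sd-of-mean across the embedded trees above `gate` -- so variables
// carrying no signal score exactly zero and are never split on; this is what
// lets a null treatment indicator stay off every routing path.
static std::vector<double> embedded_importance_impl(
    const NumericMatrix& X, const NumericVector& y, const std::vector<int>& idx,
    const std::vector<int>& cand, int embedded_trees, int embedded_depth,
    int min_node_size, double gate,
    std::vector<std::vector<double>>* deltas_out = nullptr) {
  std::vector<double> imp(X.ncol(), 0.0);
  if (deltas_out) deltas_out->assign(X.ncol(), std::vector<double>());
  const int m = (int)idx.size();
  if (m < 2 || y_constant(y, idx)) return imp;
  if (embedded_trees <= 1) {
    for (int j : cand) {
      double g, c;
      if (best_split_var(X, y, idx, j, min_node_size, g, c)) imp[j] = g;
    }
    return imp;
  }
  const int emb_min = std::max(2, min_node_size / 2);
  const int ssize = std::max(2, (int)std::ceil(0.632 * m));
  // per-candidate running sums over the embedded trees (all candidates are
  // offered to every embedded tree -- resampling rows, not features, keeps
  // the importance ranking between competing candidates low-variance; a
  // tree that leaves a candidate unused contributes an exact 0, evidence of
  // unimportance)
  std::vector<double> sum(X.ncol(), 0.0), sumsq(X.ncol(), 0.0);
  std::vector<int> cnt(X.ncol(), 0);
  const std::vector<int>& feats = cand;
  for (int t = 0; t < embedded_trees; ++t) {
    std::vector<int> sub = sample_without_replacement(idx, ssize);
    std::vector<bool> insub(X.nrow(), false);
    for (int i : sub) insub[i] = true;
    std::vector<int> oob;
    for (int i : idx) if (!insub[i]) oob.push_back(i);
    std::vector<Node> tree;
    fit_greedy_node(X, y, sub, feats, emb_min, 0, embedded_depth, tree);
    if (oob.empty()) continue;
    std::vector<bool> used(X.ncol(), false);
    for (const Node& nd : tree) if (nd.var >= 0) used[nd.var] = true;
    std::vector<double> base_pred(oob.size());
    double sse0 = 0.0;
    for (size_t i = 0; i < oob.size(); ++i) {
      base_pred[i] = predict_row(tree, X, oob[i], -1, 0.0);
      double e = y[oob[i]] - base_pred[i];
      sse0 += e * e;
    }
    for (int j : feats) {
      double delta = 0.0;
      if (used[j]) { // permuting an unused variable changes nothing
        std::vector<int> perm(oob.size());
        for (size_t i = 0; i < oob.size(); ++i) perm[i] = (int)i;
        for (size_t i = oob.size(); i > 1; --i)
          std::swap(perm[i - 1], perm[runif_int((int)i)]);
        double sse1 = 0.0;
        for (size_t i = 0; i < oob.size(); ++i) {
          double p = predict_row(tree, X, oob[i], j, X(oob[perm[i]], j));
          double e = y[oob[i]] - p;
          sse1 += e * e;
        }
        delta = (sse1 - sse0) / oob.size();
      }
      sum[j] += delta; sumsq[j] += delta * delta; ++cnt[j];
      if (deltas_out) (*deltas_out)[j].push_back(delta);
    }
  }
  for (int j : cand) {
    if (cnt[j] < 2) continue;
    const double mean = sum[j] / cnt[j];
    if (mean <= 0.0) continue;
    double var = (sumsq[j] - cnt[j] * mean * mean) / (cnt[j] - 1);
    if (var < 0.0) var = 0.0;
    // decisively nonzero: consistent positives (zero spread), or a one-sided
    // t statistic across the embedded trees exceeding the gate
    if (var == 0.0 || mean / std::sqrt(var / cnt[j]) > gate) imp[j] = mean;
  }
  return imp;
}

// ---- the outer reinforcement-learning tree ----

struct RLTParamsCpp {
  int min_node_size, embedded_trees, embedded_depth;
  double muting_rate, importance_gate;
  bool trace;
};

struct Trace {
  std::vector<std::vector<int>> cand_sets; // per node, 0-based candidate vars
  std::vector<std::vector<int>> muted;     // per node, vars muted at that node
};

static int fit_rlt_node(const NumericMatrix& X, const NumericVector& y,
                        const std::vector<int>& idx, std::vector<int> cand,
                        const RLTParamsCpp& par, std::vector<Node>& nodes,
                        Trace& tr) {
  Node nd; nd.var = -1; nd.split = 0.0; nd.left = -1; nd.right = -1;
  nd.pred = node_mean(y, idx); nd.n = (int)idx.size();
  int me = (int)nodes.size();
  nodes.push_back(nd);
  if (par.trace) {
    tr.cand_sets.push_back(cand);
    tr.muted.push_back(std::vector<int>());
  }
  if ((int)idx.size() < 2 * par.min_node_size || cand.empty() ||
      y_constant(y, idx))
    return me;
  std::vector<std::vector<double>> deltas;
  std::vector<double> imp = embedded_importance_impl(
      X, y, idx, cand, par.embedded_trees, par.embedded_depth,
      par.min_node_size, par.importance_gate, &deltas);
  // candidates ordered by importance descending, ties by lowest index
  std::vector<int> order(cand);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (imp[a] != imp[b]) return imp[a] > imp[b];
    return a < b;
  });
  // Statistical tie-break: the top candidate keeps first place only when it
  // is decisively better than every other gated-in candidate (paired t of
  // the per-embedded-tree importances above the gate). Candidates it cannot
  // be distinguished from form a tie set resolved to the lowest column
  // index; the design puts the treatment indicator last, so a treatment
  // indicator whose importance merely equals a covariate's (the typical
  // shape of a pure covariate-by-treatment interaction, which either order
  // fits equally well) defers to the covariate, keeping treatment splits as
  // deep -- as localized -- as the data allow.
  if (par.embedded_trees > 1 && order.size() > 1 && imp[order[0]] > 0.0) {
    const int top = order[0];
    int winner = top;
    for (size_t q = 1; q < order.size(); ++q) {
      const int k = order[q];
      if (imp[k] <= 0.0) break; // order is sorted: the rest are gated out
      if (k > winner) continue;
      const std::vector<double>& da = deltas[top];
      const std::vector<double>& db = deltas[k];
      if (da.size() != db.size() || da.size() < 2) continue;
      const int T = (int)da.size();
      double s = 0.0, ss = 0.0;
      for (int t = 0; t < T; ++t) {
        const double d = da[t] - db[t];
        s += d; ss += d * d;
      }
      const double mean = s / T;
      double var = (ss - T * mean * mean) / (T - 1);
      if (var < 0.0) var = 0.0;
      const bool decisive = (var == 0.0)
          ? (mean > 0.0)
          : (mean / std::sqrt(var / T) > par.importance_gate);
      if (!decisive) winner = k;
    }
    if (winner != top) {
      order.erase(std::find(order.begin(), order.end(), winner));
      order.insert(order.begin(), winner);
    }
  }
  int split_var = -1; double cut = 0.0, gain = 0.0;
  for (int j : order) {
    if (imp[j] <= 0.0) break; // zero-importance variables are never split on
    if (best_split_var(X, y, idx, j, par.min_node_size, gain, cut)) {
      split_var = j;
      break;
    }
  }
  if (split_var < 0) return me;
  // progressive muting: remove the lowest-importance fraction of the
  // remaining candidates from both children (never the split variable);
  // ties in importance mute the higher index first
  std::vector<int> remaining;
  for (int j : cand) if (j != split_var) remaining.push_back(j);
  int k = (int)std::ceil(par.muting_rate * remaining.size());
  if (k > (int)remaining.size()) k = (int)remaining.size();
  std::sort(remaining.begin(), remaining.end(), [&](int a, int b) {
    if (imp[a] != imp[b]) return imp[a] < imp[b];
    return a > b;
  });
  std::vector<bool> is_muted(X.ncol(), false);
  for (int i = 0; i < k; ++i) is_muted[remaining[i]] = true;
  std::vector<int> child_cand;
  for (int j : cand) if (!is_muted[j]) child_cand.push_back(j);
  if (par.trace)
    for (int i = 0; i < k; ++i) tr.muted[me].push_back(remaining[i]);

  std::vector<int> li, ri;
  for (int i : idx) (X(i, split_var) <= cut ? li : ri).push_back(i);
  nodes[me].var = split_var; nodes[me].split = cut;
  int l = fit_rlt_node(X, y, li, child_cand, par, nodes, tr);
  int r = fit_rlt_node(X, y, ri, child_cand, par, nodes, tr);
  nodes[me].left = l; nodes[me].right = r;
  return me;
}

static NumericMatrix nodes_to_matrix(const std::vector<Node>& nodes) {
  NumericMatrix M((int)nodes.size(), 6);
  colnames(M) = CharacterVector::create("var", "split", "left", "right",
                                        "pred", "n");
  for (size_t i = 0; i < nodes.size(); ++i) {
    const Node& nd = nodes[i];
    M(i, 0) = nd.var >= 0 ? nd.var + 1 : 0; // 1-based; 0 marks a leaf
    M(i, 1) = nd.var >= 0 ? nd.split : NA_REAL;
    M(i, 2) = nd.left >= 0 ? nd.left + 1 : 0;
    M(i, 3) = nd.right >= 0 ? nd.right + 1 : 0;
    M(i, 4) = nd.pred;
    M(i, 5) = nd.n;
  }
  return M;
}

// [[Rcpp::export]]
List rlt_fit_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                      IntegerVector candidates, int min_node_size,
                      double muting_rate, int embedded_trees,
                      int embedded_depth, double importance_gate, bool trace) {
  std::vector<int> idx(rows.begin(), rows.end());
  for (int& i : idx) --i;
  std::vector<int> cand(candidates.begin(), candidates.end());
  for (int& j : cand) --j;
  RLTParamsCpp par{min_node_size, embedded_trees, embedded_depth,
                   muting_rate, importance_gate, trace};
  std::vector<Node> nodes;
  Trace tr;
  fit_rlt_node(X, y, idx, cand, par, nodes, tr);
  List out = List::create(_["nodes"] = nodes_to_matrix(nodes));
  if (trace) {
    List cs(tr.cand_sets.size()), mu(tr.muted.size());
    for (size_t i = 0; i < tr.cand_sets.size(); ++i) {
      IntegerVector v(tr.cand_sets[i].begin(), tr.cand_sets[i].end());
      cs[i] = v + 1;
      IntegerVector w(tr.muted[i].begin(), tr.muted[i].end());
      mu[i] = w + 1;
    }
    out["candidate_sets"] = cs;
    out["muted"] = mu;
  }
  return out;
}

// [[Rcpp::export]]
List rlt_fit_forest_cpp(NumericMatrix X, NumericVector y, int n_trees,
                        double subsample_frac, int min_node_size,
                        double muting_rate, int embedded_trees,
                        int embedded_depth, double importance_gate) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  std::vector<int> cand(p);
  for (int j = 0; j < p; ++j) cand[j] = j;
  RLTParamsCpp par{min_node_size, embedded_trees, embedded_depth,
                   muting_rate, importance_gate, false};
  List trees(n_trees);
  NumericVector oob_err(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx;
    if (subsample_frac >= 1.0) idx = all;
    else idx = sample_without_replacement(all, std::max(2,
             (int)std::floor(subsample_frac * n)));
    std::vector<Node> nodes;
    Trace tr;
    fit_rlt_node(X, y, idx, cand, par, nodes, tr);
    trees[t] = nodes_to_matrix(nodes);
    std::vector<bool> insub(n, false);
    for (int i : idx) insub[i] = true;
    double sse = 0.0; int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (insub[i]) continue;
      double e = y[i] - predict_row(nodes, X, i, -1, 0.0);
      sse += e * e; ++cnt;
    }
    oob_err[t] = cnt ? sse / cnt : NA_REAL;
  }
  return List::create(_["trees"] = trees, _["oob_error"] = oob_err);
}

// [[Rcpp::export]]
NumericVector rlt_embedded_importance_cpp(NumericMatrix X, NumericVector y,
                                          IntegerVector candidates,
                                          int embedded_trees,
                                          int embedded_depth,
                                          int min_node_size,
                                          double importance_gate) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  std::vector<int> cand(candidates.begin(), candidates.end());
  for (int& j : cand) --j;
  std::vector<double> imp = embedded_importance_impl(
      X, y, idx, cand, embedded_trees, embedded_depth, min_node_size,
      importance_gate);
  return NumericVector(imp.begin(), imp.end());
}

static std::vector<Node> matrix_to_nodes(const NumericMatrix& M) {
  std::vector<Node> nodes(M.nrow());
  for (int i = 0; i < M.nrow(); ++i) {
    nodes[i].var = (int)M(i, 0) - 1;
    nodes[i].split = M(i, 1);
    nodes[i].left = (int)M(i, 2) - 1;
    nodes[i].right = (int)M(i, 3) - 1;
    nodes[i].pred = M(i, 4);
    nodes[i].n = (int)M(i, 5);
  }
  return nodes;
}

// [[Rcpp::export]]
NumericVector rlt_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    std::vector<Node> nodes = matrix_to_nodes(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += predict_row(nodes, X, i, -1, 0.0);
  }
  return out / (double)T;
}

// Counterfactual predictions: route each row with the treatment column
// forced to 1 and to 0. a_on_path flags rows whose routing (under either
// arm) passes through a split on the treatment column in any tree.
// [[Rcpp::export]]
List rlt_counterfactual_cpp(List trees, NumericMatrix X, int treat_col) {
  const int n = X.nrow(), T = trees.size();
  const int tc = treat_col - 1;
  NumericVector r1(n), r0(n);
  LogicalVector onpath(n);
  for (int t = 0; t < T; ++t) {
    std::vector<Node> nodes = matrix_to_nodes(trees[t]);
    for (int i = 0; i < n; ++i) {
      for (int arm = 0; arm <= 1; ++arm) {
        int k = 0;
        while (nodes[k].var >= 0) {
          double x;
          if (nodes[k].var == tc) { x = (double)arm; onpath[i] = true; }
          else x = X(i, nodes[k].var);
          k = (x <= nodes[k].split) ? nodes[k].left : nodes[k].right;
        }
        if (arm == 1) r1[i] += nodes[k].pred; else r0[i] += nodes[k].pred;
      }
    }
  }
  return List::create(_["r1"] = r1 / (double)T, _["r0"] = r0 / (double)T,
                      _["a_on_path"] = onpath);
}
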