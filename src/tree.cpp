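#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Binary regression tree on a {0,1} outcome.
//
// Impurity is ANOVA deviance: I = sum_i (y_i - ybar)^2 = s - s^2/n where s is
// the number of positives in the node.  Leaf prediction is the positive
// relative frequency s/n.  Splits are scored on observed values of the
// candidate covariate only; cases with the split covariate missing are routed
// with the child holding the majority of observed members (direction frozen
// at fit time).  Thresholds sit at midpoints between consecutive distinct
// observed values.  Nominal covariates are searched through the within-level
// mean ordering (exact for squared error).
//
// Tie rules: a candidate replaces the incumbent only when its gain exceeds
// the incumbent's by more than GAIN_TOL, and covariates are scanned in schema
// order with thresholds ascending, so equal-gain ties resolve to the earlier
// covariate, then the smaller threshold.

static const double GAIN_TOL = 1e-9;

// node matrix column layout (kept in sync with R side via colnames)
enum Col {
  C_PARENT = 0, C_LEFT, C_RIGHT, C_VAR, C_THRESHOLD, C_MASK, C_NOMINAL,
  C_MISSDIR, C_N, C_NPOS, C_YHAT, C_IMPURITY, C_DEPTH, C_GAIN, C_NCOL
};

static inline double node_imp(int s, int n) {
  return (double)s - (double)s * (double)s / (double)n;
}

struct SplitCand {
  int var;            // 0-based covariate index, -1 = none
  double threshold;
  int mask;           // nominal: bit (level-1) set => level routes left
  bool nominal;
  int miss_dir;       // 1 = left, 2 = right
  double gain;        // observed-only impurity decrease
};

struct Node {
  int parent, left, right;
  SplitCand split;
  int n, npos, depth;
  double yhat, impurity;
};

struct Grower {
  const NumericMatrix &X;
  const IntegerVector &y;
  const IntegerVector &kind; // 0 = numeric/ordered, 1 = nominal
  int p;
  int min_split, min_leaf, max_depth, mtry;
  double cp;
  double root_imp;
  std::vector<Node> nodes;

  Grower(const NumericMatrix &X_, const IntegerVector &y_,
         const IntegerVector &kind_, int min_split_, int min_leaf_,
         int max_depth_, double cp_, int mtry_)
      : X(X_), y(y_), kind(kind_), p(X_.ncol()), min_split(min_split_),
        min_leaf(min_leaf_), max_depth(max_depth_), cp(cp_), mtry(mtry_),
        root_imp(0.0) {}

  bool search(const std::vector<int> &rows, SplitCand &best) {
    best.var = -1;
    best.gain = 0.0;
    std::vector<int> cand(p);
    for (int j = 0; j < p; ++j) cand[j] = j;
    if (mtry < p) {
      // partial Fisher-Yates with R's RNG, then restore schema order
      for (int i = 0; i < mtry; ++i) {
        int k = i + (int)(unif_rand() * (double)(p - i));
        if (k >= p) k = p - 1;
        std::swap(cand[i], cand[k]);
      }
      cand.resize(mtry);
      std::sort(cand.begin(), cand.end());
    }

    std::vector<std::pair<double, int> > v;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int j = cand[ci];
      v.clear();
      int sobs = 0;
      for (size_t r = 0; r < rows.size(); ++r) {
        double x = X(rows[r], j);
        if (!ISNAN(x)) {
          v.push_back(std::make_pair(x, y[rows[r]]));
          sobs += y[rows[r]];
        }
      }
      int nobs = (int)v.size();
      if (nobs < 2 * min_leaf) continue;
      if (sobs == 0 || sobs == nobs) continue; // pure on observed: no gain
      double Iobs = node_imp(sobs, nobs);

      if (kind[j] == 0) {
        std::sort(v.begin(), v.end());
        int sl = 0;
        for (int i = 1; i < nobs; ++i) {
          sl += v[i - 1].second;
          if (v[i].first <= v[i - 1].first) continue; // not a boundary
          int nl = i, nr = nobs - i;
          if (nl < min_leaf || nr < min_leaf) continue;
          double gain = Iobs - node_imp(sl, nl) - node_imp(sobs - sl, nr);
          if (gain > best.gain + GAIN_TOL) {
            best.var = j;
            best.threshold = (v[i - 1].first + v[i].first) / 2.0;
            best.mask = 0;
            best.nominal = false;
            best.miss_dir = (nl >= nr) ? 1 : 2;
            best.gain = gain;
          }
        }
      } else {
        // nominal: per-level counts, order levels by within-level mean
        int maxlev = 0;
        for (int i = 0; i < nobs; ++i) {
          int lev = (int)v[i].first;
          if (lev > maxlev) maxlev = lev;
        }
        std::vector<int> cnt(maxlev + 1, 0), sum(maxlev + 1, 0);
        for (int i = 0; i < nobs; ++i) {
          int lev = (int)v[i].first;
          cnt[lev] += 1;
          sum[lev] += v[i].second;
        }
        std::vector<int> levs;
        for (int L = 1; L <= maxlev; ++L)
          if (cnt[L] > 0) levs.push_back(L);
        if (levs.size() < 2) continue;
        std::sort(levs.begin(), levs.end(), [&](int a, int b) {
          double ma = (double)sum[a] / cnt[a], mb = (double)sum[b] / cnt[b];
          if (ma != mb) return ma < mb;
          return a < b;
        });
        int nl = 0, sl = 0, mask = 0;
        for (size_t k = 0; k + 1 < levs.size(); ++k) {
          nl += cnt[levs[k]];
          sl += sum[levs[k]];
          mask |= (1 << (levs[k] - 1));
          int nr = nobs - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          double gain = Iobs - node_imp(sl, nl) - node_imp(sobs - sl, nr);
          if (gain > best.gain + GAIN_TOL) {
            best.var = j;
            best.threshold = NA_REAL;
            best.mask = mask;
            best.nominal = true;
            best.miss_dir = (nl >= nr) ? 1 : 2;
            best.gain = gain;
          }
        }
      }
    }
    return best.var >= 0;
  }

  bool goes_left(const SplitCand &s, double x) const {
    if (ISNAN(x)) return s.miss_dir == 1;
    if (s.nominal) return (s.mask >> ((int)x - 1)) & 1;
    return x < s.threshold;
  }

  int build(const std::vector<int> &rows, int parent, int depth) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    int n = (int)rows.size(), s = 0;
    for (size_t r = 0; r < rows.size(); ++r) s += y[rows[r]];
    Node &nd = nodes[id];
    nd.parent = parent;
    nd.left = nd.right = -1;
    nd.split.var = -1;
    nd.n = n;
    nd.npos = s;
    nd.depth = depth;
    nd.yhat = (double)s / (double)n;
    nd.impurity = node_imp(s, n);
    if (depth == 0) root_imp = nd.impurity;

    if (n < min_split || depth >= max_depth || s == 0 || s == n) return id;
    SplitCand best;
    if (!search(rows, best)) return id;
    if (!(best.gain > 1e-12) || best.gain < cp * root_imp - 1e-12) return id;

    std::vector<int> lrows, rrows;
    for (size_t r = 0; r < rows.size(); ++r) {
      if (goes_left(best, X(rows[r], best.var)))
        lrows.push_back(rows[r]);
      else
        rrows.push_back(rows[r]);
    }
    if (lrows.empty() || rrows.empty()) return id; // cannot happen: min_leaf
    nodes[id].split = best;
    int l = build(lrows, id, depth + 1);
    nodes[id].left = l;
    int r = build(rrows, id, depth + 1);
    nodes[id].right = r;
    return id;
  }

  NumericMatrix as_matrix() const {
    int nn = (int)nodes.size();
    NumericMatrix m(nn, C_NCOL);
    for (int i = 0; i < nn; ++i) {
      const Node &nd = nodes[i];
      m(i, C_PARENT) = nd.parent + 1;
      m(i, C_LEFT) = nd.left + 1;
      m(i, C_RIGHT) = nd.right + 1;
      bool isleaf = nd.split.var < 0;
      m(i, C_VAR) = isleaf ? 0 : nd.split.var + 1;
      m(i, C_THRESHOLD) = isleaf ? NA_REAL : nd.split.threshold;
      m(i, C_MASK) = isleaf ? 0 : nd.split.mask;
      m(i, C_NOMINAL) = (!isleaf && nd.split.nominal) ? 1 : 0;
      m(i, C_MISSDIR) = isleaf ? 0 : nd.split.miss_dir;
      m(i, C_N) = nd.n;
      m(i, C_NPOS) = nd.npos;
      m(i, C_YHAT) = nd.yhat;
      m(i, C_IMPURITY) = nd.impurity;
      m(i, C_DEPTH) = nd.depth;
      m(i, C_GAIN) = isleaf ? 0 : nd.split.gain;
    }
    colnames(m) = CharacterVector::create(
        "parent", "left", "right", "var", "threshold", "mask", "nominal",
        "miss_dir", "n", "n_pos", "yhat", "impurity", "depth", "gain");
    return m;
  }
};

// [[Rcpp::export]]
NumericMatrix grow_tree_cpp(NumericMatrix X, IntegerVector y,
                            IntegerVector kind, IntegerVector rows,
                            int min_split, int min_leaf, int max_depth,
                            double cp, int mtry) {
  Grower g(X, y, kind, min_split, min_leaf, max_depth, cp, mtry);
  std::vector<int> rr(rows.size());
  for (int i = 0; i < rows.size(); ++i) rr[i] = rows[i] - 1;
  g.build(rr, -1, 0);
  return g.as_matrix();
}

// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, IntegerVector y, IntegerVector kind,
                     int n_trees, int mtry, int min_split, int min_leaf,
                     int max_depth, bool bootstrap) {
  int n = X.nrow(), p = X.ncol();
  List trees(n_trees);
  NumericMatrix gains(n_trees, p);
  for (int t = 0; t < n_trees; ++t) {
    Grower g(X, y, kind, min_split, min_leaf, max_depth, 0.0, mtry);
    std::vector<int> rr(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int k = (int)(unif_rand() * (double)n);
        if (k >= n) k = n - 1;
        rr[i] = k;
      }
    } else {
      for (int i = 0; i < n; ++i) rr[i] = i;
    }
    g.build(rr, -1, 0);
    NumericMatrix m = g.as_matrix();
    for (int i = 0; i < m.nrow(); ++i) {
      int var = (int)m(i, C_VAR);
      if (var > 0) gains(t, var - 1) += m(i, C_GAIN);
    }
    trees[t] = m;
  }
  return List::create(Named("trees") = trees, Named("gains") = gains);
}

// Weakest-link cost-complexity pruning sequence.  Nodes are in preorder
// (children have larger indices than parents), so subtree stats are a single
// reverse pass and reachability a single forward pass.  Each step collapses
// every reachable link whose strength g(t) = (I(t) - sum leaf I below) /
// (leaves below - 1) is <= the current minimum; strengths are recomputed
// after each collapse wave, so alphas are strictly increasing.
// [[Rcpp::export]]
List cp_path_cpp(NumericMatrix nodes) {
  const double TOL = 1e-9;
  int nn = nodes.nrow();
  std::vector<char> flag(nn, 0);
  std::vector<double> nl(nn), si(nn), g(nn);
  std::vector<char> reach(nn);

  auto strengths = [&]() {
    for (int i = nn - 1; i >= 0; --i) {
      if (nodes(i, C_VAR) == 0 || flag[i]) {
        nl[i] = 1;
        si[i] = nodes(i, C_IMPURITY);
      } else {
        int l = (int)nodes(i, C_LEFT) - 1, r = (int)nodes(i, C_RIGHT) - 1;
        nl[i] = nl[l] + nl[r];
        si[i] = si[l] + si[r];
      }
    }
    for (int i = 0; i < nn; ++i) {
      if (i == 0) {
        reach[i] = 1;
      } else {
        int par = (int)nodes(i, C_PARENT) - 1;
        reach[i] = reach[par] && !flag[par] && nodes(par, C_VAR) != 0;
      }
      g[i] = R_PosInf;
      if (reach[i] && !flag[i] && nodes(i, C_VAR) != 0)
        g[i] = (nodes(i, C_IMPURITY) - si[i]) / (nl[i] - 1.0);
    }
  };
  auto collapse_to = [&](double alpha) {
    while (true) {
      strengths();
      bool hit = false;
      for (int i = 0; i < nn; ++i) {
        if (g[i] <= alpha + TOL) {
          flag[i] = 1;
          hit = true;
        }
      }
      if (!hit) break;
    }
  };

  std::vector<double> alphas;
  std::vector<std::vector<char> > flags;
  collapse_to(0.0);
  alphas.push_back(0.0);
  flags.push_back(flag);
  while (true) {
    strengths();
    double a = R_PosInf;
    for (int i = 0; i < nn; ++i)
      if (g[i] < a) a = g[i];
    if (!R_finite(a)) break;
    collapse_to(a);
    alphas.push_back(a);
    flags.push_back(flag);
  }
  int K = (int)alphas.size();
  LogicalMatrix fm(K, nn);
  NumericVector nlv(K);
  for (int k = 0; k < K; ++k) {
    flag = flags[k];
    strengths();
    nlv[k] = nl[0];
    for (int i = 0; i < nn; ++i) fm(k, i) = flags[k][i] != 0;
  }
  return List::create(Named("alphas") = NumericVector(alphas.begin(),
                                                      alphas.end()),
                      Named("flags") = fm, Named("n_leaves") = nlv);
}

// Route rows through a (possibly logically pruned) tree.  leaf_flag[i] = 1
// forces node i+1 to act as a leaf without touching the stored structure.
// [[Rcpp::export]]
NumericVector predict_tree_cpp(NumericMatrix nodes, NumericMatrix X,
                               IntegerVector leaf_flag) {
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int cur = 0;
    while (true) {
      int var = (int)nodes(cur, C_VAR);
      if (var == 0 || leaf_flag[cur] == 1) break;
      double x = X(i, var - 1);
      bool left;
      if (ISNAN(x))
        left = ((int)nodes(cur, C_MISSDIR) == 1);
      else if (nodes(cur, C_NOMINAL) == 1)
        left = (((int)nodes(cur, C_MASK) >> ((int)x - 1)) & 1) != 0;
      else
        left = (x < nodes(cur, C_THRESHOLD));
      cur = left ? (int)nodes(cur, C_LEFT) - 1 : (int)nodes(cur, C_RIGHT) - 1;
    }
    out[i] = nodes(cur, C_YHAT);
  }
  return out;
}
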