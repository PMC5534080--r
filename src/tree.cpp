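// Core recursive-partitioning engine for survival forests.
//
// Split rules:
//   0  two-sample log-rank statistic (observed - expected over pooled event
//      times, standardized by the hypergeometric variance)
//   1  log-rank-score statistic: per-subject rank scores
//      a_l = d_l - sum_{k<=l} d_k / (N - k + 1) over the time ordering
//      (events before censorings at ties), split statistic
//      |sum_left(a) - R1*abar| / sqrt(R1 (1 - R1/N) S_a^2)
//   2  conditional inference: per-node permutation-framework association test
//      of each candidate covariate against the log-rank scores (quadratic
//      form, chi-square reference; Monte-Carlo permutation p-value at small
//      nodes), Bonferroni-adjusted min-p variable selection with alpha
//      stopping, then the rule-1 split search on the selected variable only.
//
// All counts respect bootstrap multiplicity (duplicated in-bag rows).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct NodeCtx {
  std::vector<int> rows;          // bag positions, sorted by (time asc, event desc)
  int n = 0;
  int nev = 0;
  int G = 0;                      // number of distinct-time groups
  std::vector<int> gidx;          // per row -> group
  std::vector<double> Ntot, Dtot; // per group: at-risk total, deaths
  std::vector<double> scores;     // per row log-rank scores (rules 1, 2)
  double abar = 0.0, s2 = 0.0;    // score mean, sample variance (n - 1)
};

struct VarLocal {
  bool ok = false;                // >= 2 distinct values in node
  int Lv = 0;
  std::vector<double> uniq;       // sorted distinct values (global codes if unordered)
  std::vector<int> lv;            // per node row: local level 0..Lv-1
  std::vector<double> cntN, cntE, sumA; // per local level
};

struct SplitResult {
  bool found = false;
  int var = -1;                   // 0-based
  bool ordered = true;
  double threshold = 0.0;         // ordered split: x <= threshold goes left
  double left_mask = 0.0;         // unordered: bitmask of global codes going left
  double right_mask = 0.0;        // unordered: codes present in right child
  double stat = -1.0;
  int left_n = 0;
};

void build_groups(NodeCtx& ctx, const std::vector<double>& tb,
                  const std::vector<int>& eb) {
  const int n = ctx.n;
  ctx.gidx.assign(n, 0);
  int g = -1;
  double last = -1.0;
  std::vector<double> cnt, dth;
  for (int k = 0; k < n; ++k) {
    double tk = tb[ctx.rows[k]];
    if (g < 0 || tk != last) { ++g; last = tk; cnt.push_back(0); dth.push_back(0); }
    ctx.gidx[k] = g;
    cnt[g] += 1.0;
    dth[g] += eb[ctx.rows[k]];
  }
  ctx.G = g + 1;
  ctx.Dtot = dth;
  ctx.Ntot.assign(ctx.G, 0.0);
  double acc = 0.0;
  for (int j = ctx.G - 1; j >= 0; --j) { acc += cnt[j]; ctx.Ntot[j] = acc; }
}

void compute_scores(NodeCtx& ctx, const std::vector<int>& eb) {
  const int n = ctx.n;
  ctx.scores.assign(n, 0.0);
  double cum = 0.0;
  for (int k = 0; k < n; ++k) {
    const double d = eb[ctx.rows[k]];
    cum += d / (double)(n - k);
    ctx.scores[k] = d - cum;
  }
  double s = 0.0;
  for (int k = 0; k < n; ++k) s += ctx.scores[k];
  ctx.abar = s / n;
  double v = 0.0;
  for (int k = 0; k < n; ++k) {
    const double e = ctx.scores[k] - ctx.abar;
    v += e * e;
  }
  ctx.s2 = (n > 1) ? v / (n - 1) : 0.0;
}

VarLocal build_var(const NodeCtx& ctx, const std::vector<double>& xb,
                   bool need_scores) {
  VarLocal vl;
  const int n = ctx.n;
  std::vector<double> vals(n);
  for (int k = 0; k < n; ++k) vals[k] = xb[ctx.rows[k]];
  vl.uniq = vals;
  std::sort(vl.uniq.begin(), vl.uniq.end());
  vl.uniq.erase(std::unique(vl.uniq.begin(), vl.uniq.end()), vl.uniq.end());
  vl.Lv = (int)vl.uniq.size();
  if (vl.Lv < 2) return vl;
  vl.ok = true;
  vl.lv.assign(n, 0);
  vl.cntN.assign(vl.Lv, 0.0);
  vl.cntE.assign(vl.Lv, 0.0);
  vl.sumA.assign(vl.Lv, 0.0);
  for (int k = 0; k < n; ++k) {
    int l = (int)(std::lower_bound(vl.uniq.begin(), vl.uniq.end(), vals[k]) -
                  vl.uniq.begin());
    vl.lv[k] = l;
    vl.cntN[l] += 1.0;
  }
  return vl;
}

void var_event_counts(const NodeCtx& ctx, VarLocal& vl,
                      const std::vector<int>& eb, bool with_scores) {
  const int n = ctx.n;
  for (int k = 0; k < n; ++k) {
    const int l = vl.lv[k];
    vl.cntE[l] += eb[ctx.rows[k]];
    if (with_scores) vl.sumA[l] += ctx.scores[k];
  }
}

// per-group, per-level at-risk and death tables for the log-rank rule
void logrank_tables(const NodeCtx& ctx, const VarLocal& vl,
                    const std::vector<int>& eb,
                    std::vector<double>& risk, std::vector<double>& dth) {
  const int G = ctx.G, Lv = vl.Lv, n = ctx.n;
  std::vector<double> cnt(G * Lv, 0.0);
  dth.assign(G * Lv, 0.0);
  for (int k = 0; k < n; ++k) {
    const int g = ctx.gidx[k], l = vl.lv[k];
    cnt[g * Lv + l] += 1.0;
    dth[g * Lv + l] += eb[ctx.rows[k]];
  }
  risk.assign(G * Lv, 0.0);
  for (int l = 0; l < Lv; ++l) {
    double acc = 0.0;
    for (int g = G - 1; g >= 0; --g) {
      acc += cnt[g * Lv + l];
      risk[g * Lv + l] = acc;
    }
  }
}

// standardized log-rank statistic for a child defined by per-group at-risk
// n1[g] and deaths d1[g]
double logrank_stat(const NodeCtx& ctx, const std::vector<double>& n1,
                    const std::vector<double>& d1) {
  double U = 0.0, V = 0.0;
  for (int g = 0; g < ctx.G; ++g) {
    const double Ng = ctx.Ntot[g], dg = ctx.Dtot[g];
    if (dg <= 0.0 || Ng <= 1.0) continue;
    const double f = n1[g] / Ng;
    U += d1[g] - dg * f;
    V += dg * f * (1.0 - f) * (Ng - dg) / (Ng - 1.0);
  }
  if (V <= 0.0) return -1.0;
  return std::fabs(U) / std::sqrt(V);
}

double score_stat(const NodeCtx& ctx, double sumA_S, double nS) {
  const double N = ctx.n;
  const double den2 = nS * (1.0 - nS / N) * ctx.s2;
  if (den2 <= 0.0) return -1.0;
  return std::fabs(sumA_S - nS * ctx.abar) / std::sqrt(den2);
}

// search admissible splits on one variable, updating best (strict >)
void search_var(const NodeCtx& ctx, int v, VarLocal& vl,
                const std::vector<int>& eb, bool unordered_v, int rule,
                int min_node, int min_events, SplitResult& best) {
  const int Lv = vl.Lv, G = ctx.G;
  const double n = ctx.n, nev = ctx.nev;
  std::vector<double> risk, dth;
  if (rule == 0) logrank_tables(ctx, vl, eb, risk, dth);

  auto consider = [&](double nS, double eS, double stat, bool ordered,
                      double thr, double lmask, double rmask) {
    if (stat > best.stat) {
      best.found = true;
      best.var = v;
      best.ordered = ordered;
      best.threshold = thr;
      best.left_mask = lmask;
      best.right_mask = rmask;
      best.stat = stat;
      best.left_n = (int)nS;
    }
  };
  auto admissible = [&](double nS, double eS) {
    return nS >= min_node && (n - nS) >= min_node &&
           eS >= min_events && (nev - eS) >= min_events;
  };

  if (!unordered_v) {
    std::vector<double> n1(G, 0.0), d1(G, 0.0);
    double nS = 0.0, eS = 0.0, aS = 0.0;
    for (int c = 0; c < Lv - 1; ++c) {
      nS += vl.cntN[c]; eS += vl.cntE[c]; aS += vl.sumA[c];
      if (rule == 0)
        for (int g = 0; g < G; ++g) {
          n1[g] += risk[g * Lv + c];
          d1[g] += dth[g * Lv + c];
        }
      if (!admissible(nS, eS)) continue;
      const double stat = (rule == 0) ? logrank_stat(ctx, n1, d1)
                                      : score_stat(ctx, aS, nS);
      if (stat >= 0.0)
        consider(nS, eS, stat, true, (vl.uniq[c] + vl.uniq[c + 1]) / 2.0,
                 0.0, 0.0);
    }
  } else {
    // proper subsets not containing the last present level
    const int nmask = (1 << (Lv - 1)) - 1;
    std::vector<double> n1(G), d1(G);
    for (int mask = 1; mask <= nmask; ++mask) {
      double nS = 0.0, eS = 0.0, aS = 0.0;
      for (int l = 0; l < Lv - 1; ++l)
        if (mask & (1 << l)) { nS += vl.cntN[l]; eS += vl.cntE[l]; aS += vl.sumA[l]; }
      if (!admissible(nS, eS)) continue;
      double stat;
      if (rule == 0) {
        std::fill(n1.begin(), n1.end(), 0.0);
        std::fill(d1.begin(), d1.end(), 0.0);
        for (int l = 0; l < Lv - 1; ++l)
          if (mask & (1 << l))
            for (int g = 0; g < G; ++g) {
              n1[g] += risk[g * Lv + l];
              d1[g] += dth[g * Lv + l];
            }
        stat = logrank_stat(ctx, n1, d1);
      } else {
        stat = score_stat(ctx, aS, nS);
      }
      if (stat < 0.0) continue;
      long long lbits = 0, rbits = 0;
      for (int l = 0; l < Lv; ++l) {
        const long long bit = 1LL << ((long long)vl.uniq[l] - 1); // global code bit
        if (l < Lv - 1 && (mask & (1 << l))) lbits |= bit; else rbits |= bit;
      }
      const double lmask = (double)lbits, rmask = (double)rbits;
      consider(nS, eS, stat, false, 0.0, lmask, rmask);
    }
  }
}

// solve M y = z for a symmetric positive (semi)definite m x m matrix
bool solve_sym(std::vector<double> M, std::vector<double> z, int m,
               std::vector<double>& y) {
  for (int i = 0; i < m; ++i) {
    int piv = i;
    for (int r = i + 1; r < m; ++r)
      if (std::fabs(M[r * m + i]) > std::fabs(M[piv * m + i])) piv = r;
    if (std::fabs(M[piv * m + i]) < 1e-12) return false;
    if (piv != i) {
      for (int c = 0; c < m; ++c) std::swap(M[i * m + c], M[piv * m + c]);
      std::swap(z[i], z[piv]);
    }
    const double d = M[i * m + i];
    for (int r = i + 1; r < m; ++r) {
      const double f = M[r * m + i] / d;
      for (int c = i; c < m; ++c) M[r * m + c] -= f * M[i * m + c];
      z[r] -= f * z[i];
    }
  }
  y.assign(m, 0.0);
  for (int i = m - 1; i >= 0; --i) {
    double s = z[i];
    for (int c = i + 1; c < m; ++c) s -= M[i * m + c] * y[c];
    y[i] = s / M[i * m + i];
  }
  return true;
}

// quadratic-form association statistic of one covariate vs the node scores
// (chi-square reference; df = levels - 1 for categorical covariates, 1 for
// ordered covariates, which enter linearly through their numeric values)
bool quad_test(const NodeCtx& ctx, const VarLocal& vl, bool linear,
               double& stat, int& df) {
  const double N = ctx.n;
  if (vl.Lv < 2 || ctx.s2 <= 0.0) return false;
  if (linear) {
    double sx = 0.0, sxx = 0.0, T = 0.0;
    for (int l = 0; l < vl.Lv; ++l) {
      sx += vl.cntN[l] * vl.uniq[l];
      sxx += vl.cntN[l] * vl.uniq[l] * vl.uniq[l];
      T += vl.uniq[l] * vl.sumA[l];
    }
    const double ssx = sxx - sx * sx / N;
    if (ssx <= 0.0) return false;
    const double z = T - sx * ctx.abar;
    stat = z * z / (ssx * ctx.s2);
    df = 1;
    return true;
  }
  const int m = vl.Lv - 1;
  std::vector<double> z(m), M(m * m);
  for (int i = 0; i < m; ++i) {
    z[i] = vl.sumA[i] - vl.cntN[i] * ctx.abar;
    for (int j = 0; j < m; ++j)
      M[i * m + j] = ctx.s2 *
        ((i == j ? vl.cntN[i] : 0.0) - vl.cntN[i] * vl.cntN[j] / N);
  }
  std::vector<double> y;
  if (!solve_sym(M, z, m, y)) return false;
  double q = 0.0;
  for (int i = 0; i < m; ++i) q += z[i] * y[i];
  stat = std::max(q, 0.0);
  df = m;
  return true;
}

// Monte-Carlo permutation p-value for the association statistic
double perm_pvalue(const NodeCtx& ctx, const VarLocal& vl, bool linear,
                   double qobs, int n_perm) {
  const int n = ctx.n;
  const double N = ctx.n;
  if (linear) {
    double sx = 0.0, sxx = 0.0;
    for (int l = 0; l < vl.Lv; ++l) {
      sx += vl.cntN[l] * vl.uniq[l];
      sxx += vl.cntN[l] * vl.uniq[l] * vl.uniq[l];
    }
    const double ssx = sxx - sx * sx / N;
    std::vector<double> a(ctx.scores);
    int hits = 0;
    for (int b = 0; b < n_perm; ++b) {
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(a[i], a[j]);
      }
      double T = 0.0;
      for (int k = 0; k < n; ++k) T += vl.uniq[vl.lv[k]] * a[k];
      const double z = T - sx * ctx.abar;
      if (z * z / (ssx * ctx.s2) >= qobs - 1e-12) ++hits;
    }
    return (1.0 + hits) / (1.0 + n_perm);
  }
  const int m = vl.Lv - 1;
  std::vector<double> M(m * m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      M[i * m + j] = ctx.s2 *
        ((i == j ? vl.cntN[i] : 0.0) - vl.cntN[i] * vl.cntN[j] / N);
  // invert once by solving against unit vectors
  std::vector<double> Minv(m * m);
  for (int c = 0; c < m; ++c) {
    std::vector<double> e(m, 0.0), y;
    e[c] = 1.0;
    if (!solve_sym(M, e, m, y)) return NA_REAL;
    for (int r = 0; r < m; ++r) Minv[r * m + c] = y[r];
  }
  std::vector<double> a(ctx.scores);
  std::vector<double> sumA(m);
  int hits = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(a[i], a[j]);
    }
    std::fill(sumA.begin(), sumA.end(), 0.0);
    for (int k = 0; k < n; ++k)
      if (vl.lv[k] < m) sumA[vl.lv[k]] += a[k];
    double q = 0.0;
    for (int i = 0; i < m; ++i) {
      const double zi = sumA[i] - vl.cntN[i] * ctx.abar;
      for (int j = 0; j < m; ++j)
        q += zi * Minv[i * m + j] * (sumA[j] - vl.cntN[j] * ctx.abar);
    }
    if (q >= qobs - 1e-12) ++hits;
  }
  return (1.0 + hits) / (1.0 + n_perm);
}

std::vector<int> draw_candidates(int p, int mtry) {
  std::vector<int> idx(p);
  for (int i = 0; i < p; ++i) idx[i] = i;
  const int m = std::min(mtry, p);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(m);
  std::sort(idx.begin(), idx.end());
  return idx;
}

} // namespace

// [[Rcpp::export]]
List grow_tree_cpp(NumericVector time, IntegerVector event, NumericMatrix X,
                   LogicalVector unordered, IntegerVector inbag, int rule,
                   int mtry, int min_node, int min_events, double alpha,
                   int perm_small_n, int n_perm) {
  const int nb = inbag.size(), p = X.ncol();
  std::vector<double> tb(nb);
  std::vector<int> eb(nb), rowix(nb);
  for (int i = 0; i < nb; ++i) {
    rowix[i] = inbag[i] - 1;
    tb[i] = time[rowix[i]];
    eb[i] = event[rowix[i]];
  }
  std::vector<std::vector<double>> xb(p, std::vector<double>(nb));
  for (int v = 0; v < p; ++v)
    for (int i = 0; i < nb; ++i) xb[v][i] = X(rowix[i], v);

  std::vector<int> root(nb);
  for (int i = 0; i < nb; ++i) root[i] = i;
  std::stable_sort(root.begin(), root.end(), [&](int a, int b) {
    if (tb[a] != tb[b]) return tb[a] < tb[b];
    return eb[a] > eb[b];
  });

  std::vector<std::vector<int>> nodeRows;
  nodeRows.push_back(std::move(root));
  std::vector<int> splitVar, childL, childR, nNode, nEvents, leftBig;
  std::vector<double> splitVal, leftMask, rightMask, splitStat;

  for (size_t i = 0; i < nodeRows.size(); ++i) {
    NodeCtx ctx;
    ctx.rows = nodeRows[i];
    ctx.n = (int)ctx.rows.size();
    ctx.nev = 0;
    for (int k = 0; k < ctx.n; ++k) ctx.nev += eb[ctx.rows[k]];

    splitVar.push_back(0); splitVal.push_back(NA_REAL);
    leftMask.push_back(NA_REAL); rightMask.push_back(NA_REAL);
    childL.push_back(0); childR.push_back(0); leftBig.push_back(1);
    nNode.push_back(ctx.n); nEvents.push_back(ctx.nev);
    splitStat.push_back(NA_REAL);

    if (ctx.n < 2 * min_node || ctx.nev < 2 * min_events) continue;

    build_groups(ctx, tb, eb);
    if (rule != 0) compute_scores(ctx, eb);

    std::vector<int> cand = draw_candidates(p, mtry);
    SplitResult best;

    if (rule == 2) {
      // step 1: association tests, Bonferroni min-p selection
      int tested = 0, selvar = -1;
      double minp = 2.0;
      std::vector<VarLocal> locals(cand.size());
      for (size_t c = 0; c < cand.size(); ++c) {
        locals[c] = build_var(ctx, xb[cand[c]], true);
        if (!locals[c].ok) continue;
        var_event_counts(ctx, locals[c], eb, true);
        const bool linear = !unordered[cand[c]] && locals[c].Lv > 2;
        double stat; int df;
        if (!quad_test(ctx, locals[c], linear, stat, df)) continue;
        ++tested;
        double pval = (ctx.n < perm_small_n)
          ? perm_pvalue(ctx, locals[c], linear, stat, n_perm)
          : R::pchisq(stat, (double)df, 0, 0);
        if (pval < minp) { minp = pval; selvar = (int)c; }
      }
      if (selvar < 0 || std::min(1.0, minp * tested) > alpha) continue;
      search_var(ctx, cand[selvar], locals[selvar], eb,
                 unordered[cand[selvar]], 1, min_node, min_events, best);
    } else {
      for (size_t c = 0; c < cand.size(); ++c) {
        VarLocal vl = build_var(ctx, xb[cand[c]], rule == 1);
        if (!vl.ok) continue;
        var_event_counts(ctx, vl, eb, rule == 1);
        search_var(ctx, cand[c], vl, eb, unordered[cand[c]], rule,
                   min_node, min_events, best);
      }
    }
    if (!best.found) continue;

    // partition rows (stable, preserving the time ordering)
    std::vector<int> lrows, rrows;
    const std::vector<double>& xv = xb[best.var];
    for (int k = 0; k < ctx.n; ++k) {
      const int r = ctx.rows[k];
      bool goleft;
      if (best.ordered) goleft = xv[r] <= best.threshold;
      else goleft = (((long long)best.left_mask >> ((long long)xv[r] - 1)) & 1LL) == 1LL;
      if (goleft) lrows.push_back(r); else rrows.push_back(r);
    }
    splitVar[i] = best.var + 1;
    splitStat[i] = best.stat;
    if (best.ordered) splitVal[i] = best.threshold;
    else { leftMask[i] = best.left_mask; rightMask[i] = best.right_mask; }
    leftBig[i] = lrows.size() >= rrows.size() ? 1 : 0;
    childL[i] = (int)nodeRows.size() + 1;          // 1-based ids
    nodeRows.push_back(std::move(lrows));
    childR[i] = (int)nodeRows.size() + 1;
    nodeRows.push_back(std::move(rrows));
    nodeRows[i].clear();
  }

  const int nn = (int)splitVar.size();
  std::vector<int> termId(nn, 0);
  List members;
  int tid = 0;
  for (int i = 0; i < nn; ++i) {
    if (splitVar[i] != 0) continue;
    termId[i] = ++tid;
    IntegerVector mem(nodeRows[i].size());
    for (size_t k = 0; k < nodeRows[i].size(); ++k)
      mem[k] = rowix[nodeRows[i][k]] + 1;          // original 1-based rows
    members.push_back(mem);
  }
  return List::create(
    _["split_var"] = wrap(splitVar), _["split_value"] = wrap(splitVal),
    _["left_mask"] = wrap(leftMask), _["right_mask"] = wrap(rightMask),
    _["left_bigger"] = wrap(leftBig), _["child_left"] = wrap(childL),
    _["child_right"] = wrap(childR), _["n_node"] = wrap(nNode),
    _["n_events"] = wrap(nEvents), _["split_stat"] = wrap(splitStat),
    _["terminal_id"] = wrap(termId), _["members"] = members);
}

// [[Rcpp::export]]
List node_best_split_cpp(NumericVector time, IntegerVector event,
                         NumericMatrix X, LogicalVector unordered,
                         IntegerVector candidate_vars, int rule,
                         int min_node, int min_events) {
  const int n = time.size(), p = X.ncol();
  std::vector<double> tb(time.begin(), time.end());
  std::vector<int> eb(event.begin(), event.end());
  std::vector<std::vector<double>> xb(p, std::vector<double>(n));
  for (int v = 0; v < p; ++v)
    for (int i = 0; i < n; ++i) xb[v][i] = X(i, v);
  NodeCtx ctx;
  ctx.rows.resize(n);
  for (int i = 0; i < n; ++i) ctx.rows[i] = i;
  std::stable_sort(ctx.rows.begin(), ctx.rows.end(), [&](int a, int b) {
    if (tb[a] != tb[b]) return tb[a] < tb[b];
    return eb[a] > eb[b];
  });
  ctx.n = n;
  ctx.nev = 0;
  for (int i = 0; i < n; ++i) ctx.nev += eb[i];
  build_groups(ctx, tb, eb);
  if (rule != 0) compute_scores(ctx, eb);
  SplitResult best;
  for (int c = 0; c < candidate_vars.size(); ++c) {
    const int v = candidate_vars[c] - 1;
    VarLocal vl = build_var(ctx, xb[v], rule == 1);
    if (!vl.ok) continue;
    var_event_counts(ctx, vl, eb, rule == 1);
    search_var(ctx, v, vl, eb, unordered[v], rule, min_node, min_events, best);
  }
  if (!best.found) return List::create(_["found"] = false);
  return List::create(_["found"] = true, _["var"] = best.var + 1,
                      _["ordered"] = best.ordered,
                      _["threshold"] = best.threshold,
                      _["left_mask"] = best.left_mask,
                      _["right_mask"] = best.right_mask,
                      _["stat"] = best.stat, _["left_n"] = best.left_n);
}

// [[Rcpp::export]]
IntegerVector predict_terminal_cpp(List tree, NumericMatrix X) {
  IntegerVector splitVar = tree["split_var"];
  NumericVector splitVal = tree["split_value"];
  NumericVector lmask = tree["left_mask"], rmask = tree["right_mask"];
  IntegerVector leftBig = tree["left_bigger"];
  IntegerVector childL = tree["child_left"], childR = tree["child_right"];
  IntegerVector termId = tree["terminal_id"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (splitVar[node] != 0) {
      const int v = splitVar[node] - 1;
      const double x = X(i, v);
      bool goleft;
      if (!NumericVector::is_na(splitVal[node])) {
        goleft = ISNAN(x) ? (leftBig[node] == 1) : (x <= splitVal[node]);
      } else if (ISNAN(x) || x < 1.0) {
        goleft = leftBig[node] == 1;
      } else {
        const long long shift = (long long)x - 1;
        const bool inL = ((long long)lmask[node] >> shift) & 1LL;
        const bool inR = ((long long)rmask[node] >> shift) & 1LL;
        goleft = inL ? true : (inR ? false : leftBig[node] == 1);
      }
      node = (goleft ? childL[node] : childR[node]) - 1;
    }
    out[i] = termId[node];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix terminal_chf_cpp(List members, NumericVector time,
                               IntegerVector event, NumericVector eval_times) {
  const int nt = members.size(), ne = eval_times.size();
  NumericMatrix out(nt, ne);
  for (int t = 0; t < nt; ++t) {
    IntegerVector mem = members[t];
    const int m = mem.size();
    std::vector<int> ord(m);
    for (int i = 0; i < m; ++i) ord[i] = mem[i] - 1;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return time[a] < time[b]; });
    double H = 0.0;
    int i = 0, j = 0;
    double atrisk = m;
    while (j < ne) {
      if (i < m && time[ord[i]] <= eval_times[j]) {
        // process tie group at time[ord[i]]
        const double tt = time[ord[i]];
        double d = 0.0, c = 0.0;
        while (i < m && time[ord[i]] == tt) {
          if (event[ord[i]] == 1) d += 1.0; else c += 1.0;
          ++i;
        }
        if (d > 0.0 && atrisk > 0.0) H += d / atrisk;
        atrisk -= d + c;
      } else {
        out(t, j) = H;
        ++j;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix ensemble_chf_cpp(IntegerMatrix term_ids, List per_tree_chf,
                               Nullable<IntegerMatrix> use_) {
  const int n = term_ids.nrow(), ntree = term_ids.ncol();
  NumericMatrix first = per_tree_chf[0];
  const int ne = first.ncol();
  NumericMatrix out(n, ne);
  std::vector<int> used(n, 0);
  const bool restrict = use_.isNotNull();
  IntegerMatrix use = restrict ? IntegerMatrix(use_) : IntegerMatrix(0, 0);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix H = per_tree_chf[t];
    for (int i = 0; i < n; ++i) {
      if (restrict && use(i, t) == 0) continue;
      const int tid = term_ids(i, t) - 1;
      for (int j = 0; j < ne; ++j) out(i, j) += H(tid, j);
      ++used[i];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < ne; ++j)
      out(i, j) = used[i] > 0 ? out(i, j) / used[i] : NA_REAL;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cif_weight_matrix_cpp(IntegerMatrix train_terms,
                                    IntegerMatrix test_terms,
                                    IntegerMatrix inbag,
                                    Nullable<IntegerMatrix> use_) {
  const int n_train = train_terms.nrow(), n_test = test_terms.nrow();
  const int ntree = train_terms.ncol();
  const bool restrict = use_.isNotNull();
  IntegerMatrix use = restrict ? IntegerMatrix(use_) : IntegerMatrix(0, 0);
  NumericMatrix W(n_test, n_train);
  for (int t = 0; t < ntree; ++t) {
    int maxterm = 0;
    for (int i = 0; i < n_train; ++i)
      if (train_terms(i, t) > maxterm) maxterm = train_terms(i, t);
    std::vector<std::vector<int>> bucket_train(maxterm);
    std::vector<double> size(maxterm, 0.0);
    for (int i = 0; i < n_train; ++i) {
      const int c = inbag(i, t);
      if (c <= 0) continue;
      const int tm = train_terms(i, t) - 1;
      bucket_train[tm].push_back(i);
      size[tm] += c;
    }
    for (int j = 0; j < n_test; ++j) {
      if (restrict && use(j, t) == 0) continue;
      const int tm = test_terms(j, t) - 1;
      if (tm < 0 || tm >= maxterm || size[tm] <= 0.0) continue;
      const double w = 1.0 / size[tm];
      for (int i : bucket_train[tm]) W(j, i) += w * inbag(i, t);
    }
  }
  return W;
}

// [[Rcpp::export]]
NumericMatrix weighted_km_cpp(NumericMatrix W, NumericVector time,
                              IntegerVector event, NumericVector eval_times) {
  const int n_test = W.nrow(), n = W.ncol(), ne = eval_times.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return time[a] < time[b]; });
  // distinct-time group boundaries over the ordered training subjects
  std::vector<int> gstart;
  for (int i = 0; i < n; ++i)
    if (i == 0 || time[ord[i]] != time[ord[i - 1]]) gstart.push_back(i);
  gstart.push_back(n);
  const int G = (int)gstart.size() - 1;
  NumericMatrix out(n_test, ne);
  for (int j = 0; j < n_test; ++j) {
    double atrisk = 0.0;
    for (int i = 0; i < n; ++i) atrisk += W(j, i);
    double S = 1.0;
    int e = 0;
    for (int g = 0; g < G && e < ne; ++g) {
      const double tt = time[ord[gstart[g]]];
      while (e < ne && eval_times[e] < tt) out(j, e++) = S;
      double dw = 0.0, aw = 0.0;
      for (int i = gstart[g]; i < gstart[g + 1]; ++i) {
        const double w = W(j, ord[i]);
        aw += w;
        if (event[ord[i]] == 1) dw += w;
      }
      if (atrisk > 0.0 && dw > 0.0) S *= std::max(0.0, 1.0 - dw / atrisk);
      atrisk -= aw;
    }
    while (e < ne) out(j, e++) = S;
  }
  return out;
}
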