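// Core dynamic programs for minisatellite map analysis:
//  * interval DP for minimum-cost single-copy duplication histories,
//  * run-explanation costs (left-generated prefix / indel middle /
//    right-generated suffix) between consecutive matched units,
//  * optimal pairwise map alignment over monotone matchings.
//
// Conventions: unit symbols are 0-based integers into the alphabet; map
// positions are 1-based in the alignment DP (0 / n+1 are "no flank"
// sentinels).  dc is the min-plus-closed mutation cost matrix, so one
// effective mutation per derivation node suffices.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = 1e100;
static const double TOL = 1e-9;

// D[(i*(n+1)+j)*sigma + c] = min cost of deriving units [i,j) (0-based,
// half-open) from a single seed unit of type c.
static inline size_t dix(int i, int j, int c, int n, int sigma) {
  return ((size_t)i * (n + 1) + j) * (size_t)sigma + c;
}

static void build_deriv(const std::vector<int>& s, const NumericMatrix& dc,
                        double cdup, std::vector<double>& D) {
  const int n = (int)s.size();
  const int sigma = dc.nrow();
  D.assign((size_t)(n + 1) * (n + 1) * sigma, INF);
  std::vector<double> E(sigma);
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len <= n; ++i) {
      const int j = i + len;
      if (len == 1) {
        for (int c = 0; c < sigma; ++c) D[dix(i, j, c, n, sigma)] = dc(c, s[i]);
        continue;
      }
      for (int c2 = 0; c2 < sigma; ++c2) {
        double best = INF;
        for (int k = i + 1; k < j; ++k) {
          const double v = D[dix(i, k, c2, n, sigma)] + D[dix(k, j, c2, n, sigma)];
          if (v < best) best = v;
        }
        E[c2] = cdup + best;
      }
      for (int c = 0; c < sigma; ++c) {
        double best = INF;
        for (int c2 = 0; c2 < sigma; ++c2) {
          const double v = dc(c, c2) + E[c2];
          if (v < best) best = v;
        }
        D[dix(i, j, c, n, sigma)] = best;
      }
    }
  }
}

// Generation cost of run units [i,j) (0-based half-open) as offspring of a
// persistent flanking seed of type c.  Collapses to cdup + D because a
// partition into direct-child blocks is itself a split of the derivation
// interval DP with an unmutated root.
static inline double gen_cost(const std::vector<double>& D, int i, int j, int c,
                              int n, int sigma, double cdup) {
  if (i >= j) return 0.0;
  return cdup + D[dix(i, j, c, n, sigma)];
}

// Alignment modes: 0 = both directions, 1 = left-to-right only (runs may be
// generated only from their left flank), 2 = right-to-left only.
enum { MODE_BOTH = 0, MODE_LR = 1, MODE_RL = 2 };

// Minimum explanation cost of the run strictly between match positions p and
// i (1-based; p = 0 means no left flank, i = n+1 means no right flank).
// Optionally reports the chosen split: left-generated prefix = p+1..x,
// indel middle = x+1..y, right-generated suffix = y+1..i-1 (1-based incl.).
static double run_cost(const std::vector<int>& s, const std::vector<double>& D,
                       const std::vector<double>& wsum, double cdup, double cid,
                       int mode, int p, int i, int* out_x = 0, int* out_y = 0) {
  const int n = (int)s.size();
  const int sigma = (int)(D.size() / ((size_t)(n + 1) * (n + 1)));
  const int L = p + 1, R = i - 1;  // run interval, 1-based inclusive
  double best = INF;
  int bx = p, by = R;
  if (L > R) { if (out_x) *out_x = p; if (out_y) *out_y = R; return 0.0; }
  const bool has_lf = p >= 1, has_rf = i <= n;
  for (int x = p; x <= R; ++x) {
    if (x > p && (!has_lf || mode == MODE_RL)) break;  // prefix must stay empty
    const double gl = (x == p) ? 0.0
                               : gen_cost(D, L - 1, x, s[p - 1], n, sigma, cdup);
    for (int y = x; y <= R; ++y) {
      if (y < R && (!has_rf || mode == MODE_LR)) continue;  // suffix must stay empty
      const double gr = (y == R) ? 0.0
                                 : gen_cost(D, y, R, s[i - 1], n, sigma, cdup);
      const double v = gl + cid * (wsum[y] - wsum[x]) + gr;
      if (v < best - TOL) { best = v; bx = x; by = y; }
    }
  }
  if (out_x) *out_x = bx;
  if (out_y) *out_y = by;
  return best;
}

// Full (n+2)x(n+2) run-cost table: RC(p, i) for 0 <= p < i <= n+1.
static void build_rc(const std::vector<int>& s, const std::vector<double>& D,
                     const std::vector<double>& wsum, double cdup, double cid,
                     int mode, std::vector<double>& RC) {
  const int n = (int)s.size();
  RC.assign((size_t)(n + 2) * (n + 2), INF);
  for (int p = 0; p <= n; ++p)
    for (int i = p + 1; i <= n + 1; ++i)
      RC[(size_t)p * (n + 2) + i] = run_cost(s, D, wsum, cdup, cid, mode, p, i);
}

static std::vector<int> as_units(const IntegerVector& v) {
  std::vector<int> s(v.size());
  for (int k = 0; k < v.size(); ++k) s[k] = v[k] - 1;  // R passes 1-based codes
  return s;
}

static std::vector<double> weight_prefix(const NumericVector& wt, int n) {
  std::vector<double> wsum(n + 1, 0.0);
  for (int k = 0; k < n; ++k) wsum[k + 1] = wsum[k] + (wt.size() ? wt[k] : 1.0);
  return wsum;
}

// [[Rcpp::export(name = ".cpp_deriv_table")]]
NumericVector cpp_deriv_table(IntegerVector units, NumericMatrix dc, double cdup) {
  std::vector<int> s = as_units(units);
  const int n = (int)s.size(), sigma = dc.nrow();
  std::vector<double> D;
  build_deriv(s, dc, cdup, D);
  NumericVector out((size_t)n * n * sigma);
  out.attr("dim") = IntegerVector::create(n, n, sigma);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      for (int c = 0; c < sigma; ++c)
        out[(size_t)c * n * n + (size_t)j * n + i] = D[dix(i, j + 1, c, n, sigma)];
  return out;
}

// [[Rcpp::export(name = ".cpp_run_explain")]]
List cpp_run_explain(IntegerVector units, NumericMatrix dc, double cdup,
                     double cid, NumericVector wt, int mode, int p, int i) {
  std::vector<int> s = as_units(units);
  std::vector<double> D;
  build_deriv(s, dc, cdup, D);
  std::vector<double> wsum = weight_prefix(wt, (int)s.size());
  int x, y;
  double cost = run_cost(s, D, wsum, cdup, cid, mode, p, i, &x, &y);
  return List::create(_["cost"] = cost, _["x"] = x, _["y"] = y);
}

struct MapTables {
  std::vector<int> s;
  std::vector<double> D, wsum;
  std::vector<double> RC;  // for this map's indel-cost role
};

static double pair_cost_dp(const MapTables& A, const MapTables& B,
                           const NumericMatrix& dc, double cins, double cdel,
                           std::vector<double>* Mout = 0,
                           std::vector<int>* NMout = 0,
                           std::vector<int>* PPout = 0,
                           std::vector<int>* PQout = 0,
                           int* fi_out = 0, int* fj_out = 0) {
  const int n = (int)A.s.size(), m = (int)B.s.size();
  const int n2 = n + 2, m2 = m + 2;
  std::vector<double> M((size_t)(n + 1) * (m + 1), INF);
  std::vector<int> NM((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> PP((size_t)(n + 1) * (m + 1), 0), PQ((size_t)(n + 1) * (m + 1), 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = A.RC[(size_t)0 * n2 + i] + B.RC[(size_t)0 * m2 + j];
      int bnm = 0, bp = 0, bq = 0;
      for (int p = 1; p < i; ++p) {
        const double rca = A.RC[(size_t)p * n2 + i];
        for (int q = 1; q < j; ++q) {
          const double v = M[(size_t)p * (m + 1) + q] + rca + B.RC[(size_t)q * m2 + j];
          const int nm = NM[(size_t)p * (m + 1) + q];
          if (v < best - TOL || (v < best + TOL && nm > bnm)) {
            best = v; bnm = nm; bp = p; bq = q;
          }
        }
      }
      M[(size_t)i * (m + 1) + j] = dc(A.s[i - 1], B.s[j - 1]) + best;
      NM[(size_t)i * (m + 1) + j] = bnm + 1;
      PP[(size_t)i * (m + 1) + j] = bp;
      PQ[(size_t)i * (m + 1) + j] = bq;
    }
  }
  // terminal: no-match candidate vs best last match
  double best = cdel * A.wsum[n] + cins * B.wsum[m];
  int bnm = 0, fi = 0, fj = 0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      const double v = M[(size_t)i * (m + 1) + j] + A.RC[(size_t)i * n2 + (n + 1)] +
                       B.RC[(size_t)j * m2 + (m + 1)];
      const int nm = NM[(size_t)i * (m + 1) + j];
      if (v < best - TOL || (v < best + TOL && nm > bnm)) {
        best = v; bnm = nm; fi = i; fj = j;
      }
    }
  if (Mout) { *Mout = M; *NMout = NM; *PPout = PP; *PQout = PQ; *fi_out = fi; *fj_out = fj; }
  return best;
}

static MapTables make_tables(const IntegerVector& units, const NumericMatrix& dc,
                             double cdup, double cid, const NumericVector& wt,
                             int mode) {
  MapTables T;
  T.s = as_units(units);
  build_deriv(T.s, dc, cdup, T.D);
  T.wsum = weight_prefix(wt, (int)T.s.size());
  build_rc(T.s, T.D, T.wsum, cdup, cid, mode, T.RC);
  return T;
}

// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(IntegerVector a, IntegerVector b, NumericMatrix dc,
                    double cdup, double cins, double cdel, NumericVector wta,
                    NumericVector wtb, int mode) {
  MapTables A = make_tables(a, dc, cdup, cdel, wta, mode);
  MapTables B = make_tables(b, dc, cdup, cins, wtb, mode);
  const int n = (int)A.s.size(), m = (int)B.s.size();
  std::vector<double> M;
  std::vector<int> NM, PP, PQ;
  int fi, fj;
  double total = pair_cost_dp(A, B, dc, cins, cdel, &M, &NM, &PP, &PQ, &fi, &fj);

  // traceback matches
  std::vector<int> mi, mj;
  int ci = fi, cj = fj;
  while (ci > 0) {
    mi.push_back(ci); mj.push_back(cj);
    const int p = PP[(size_t)ci * (m + 1) + cj], q = PQ[(size_t)ci * (m + 1) + cj];
    ci = p; cj = q;
  }
  std::reverse(mi.begin(), mi.end());
  std::reverse(mj.begin(), mj.end());
  const int k = (int)mi.size();

  IntegerMatrix matches(k, 2);
  NumericVector mcost(k);
  for (int t = 0; t < k; ++t) {
    matches(t, 0) = mi[t]; matches(t, 1) = mj[t];
    mcost[t] = dc(A.s[mi[t] - 1], B.s[mj[t] - 1]);
  }

  // runs between consecutive matches (incl. leading/trailing)
  std::vector<int> r_map, r_start, r_end, r_x, r_y, r_lf, r_rf;
  std::vector<double> r_cost;
  auto add_runs = [&](const MapTables& T, int which, int len,
                      const std::vector<int>& mm) {
    const double cid = (which == 1) ? cdel : cins;
    int prev = 0;
    for (size_t t = 0; t <= mm.size(); ++t) {
      const int nxt = (t < mm.size()) ? mm[t] : len + 1;
      if (nxt - prev - 1 > 0) {
        int x, y;
        const double c =
            run_cost(T.s, T.D, T.wsum, cdup, cid, mode, prev, nxt, &x, &y);
        r_map.push_back(which);
        r_start.push_back(prev + 1); r_end.push_back(nxt - 1);
        r_x.push_back(x); r_y.push_back(y);
        r_lf.push_back(prev >= 1 ? prev : 0);
        r_rf.push_back(nxt <= len ? nxt : 0);
        r_cost.push_back(c);
      }
      prev = nxt;
    }
  };
  add_runs(A, 1, n, mi);
  add_runs(B, 2, m, mj);

  return List::create(
      _["total"] = total, _["matches"] = matches, _["match_costs"] = mcost,
      _["run_map"] = wrap(r_map), _["run_start"] = wrap(r_start),
      _["run_end"] = wrap(r_end), _["run_x"] = wrap(r_x), _["run_y"] = wrap(r_y),
      _["run_lf"] = wrap(r_lf), _["run_rf"] = wrap(r_rf),
      _["run_cost"] = wrap(r_cost));
}

// [[Rcpp::export(name = ".cpp_pairwise")]]
NumericMatrix cpp_pairwise(List maps, NumericMatrix dc, double cdup,
                           double cins, double cdel, List wts, int mode) {
  const int nmap = maps.size();
  const bool same_cid = std::abs(cins - cdel) < TOL;
  std::vector<MapTables> Tdel(nmap), Tins;
  if (!same_cid) Tins.resize(nmap);
  for (int k = 0; k < nmap; ++k) {
    IntegerVector u = maps[k];
    NumericVector w = wts[k];
    Tdel[k] = make_tables(u, dc, cdup, cdel, w, mode);
    if (!same_cid) Tins[k] = make_tables(u, dc, cdup, cins, w, mode);
  }
  NumericMatrix out(nmap, nmap);
  for (int i = 0; i < nmap; ++i)
    for (int j = i + 1; j < nmap; ++j) {
      const MapTables& A = Tdel[i];
      const MapTables& B = same_cid ? Tdel[j] : Tins[j];
      const double v = pair_cost_dp(A, B, dc, cins, cdel);
      out(i, j) = v; out(j, i) = v;
    }
  return out;
}
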