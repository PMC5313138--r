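#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap pairwise dynamic programming (Gotoh), three modes:
//   mode 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch),
//   mode 2 = overlap (global with free end gaps on both sequences).
// A gap of length k costs gap_open + k * gap_extend.
// Traceback ties: diagonal (M) > up/gap-in-b (X) > left/gap-in-a (Y).
//
// Sequences arrive as 0-based integer codes indexing the score matrix.
// When `pssm` has rows, position i of `a` is scored by pssm(i, b[j])
// and `a` itself is only used for its length / identity bookkeeping.

static const double NEG_INF = -1e30;

struct AlnResult {
  double score;
  int a_start, a_end, b_start, b_end;     // 0-based half-open spans
  std::vector<int> ai, bi;                // per column: index or -1 (gap)
};

static AlnResult gotoh(const IntegerVector& a, const IntegerVector& b,
                       const NumericMatrix& S, const NumericMatrix& pssm,
                       bool use_pssm, double go, double ge, int mode) {
  const int n = use_pssm ? pssm.nrow() : a.size();
  const int m = b.size();
  AlnResult res; res.score = 0;
  res.a_start = res.a_end = res.b_start = res.b_end = 0;
  if (n == 0 || m == 0) {
    if (mode == 1 || mode == 2) { // pure gap alignment
      res.score = (n + m == 0) ? 0 : ((mode == 2) ? 0 : -(go + (n + m) * ge));
      for (int i = 0; i < n; ++i) { res.ai.push_back(i); res.bi.push_back(-1); }
      for (int j = 0; j < m; ++j) { res.ai.push_back(-1); res.bi.push_back(j); }
      res.a_end = n; res.b_end = m;
    }
    return res;
  }

  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF),
                      X((size_t)(n + 1) * W, NEG_INF),
                      Y((size_t)(n + 1) * W, NEG_INF);
  // traceback codes -- M: 0 diag-from-M, 1 diag-from-X, 2 diag-from-Y,
  //                   3 local/overlap start; X: 0 from M, 1 from X;
  //                   Y: 0 from M, 1 from Y
  std::vector<uint8_t> tM((size_t)(n + 1) * W, 3), tX((size_t)(n + 1) * W, 0),
                       tY((size_t)(n + 1) * W, 0);
  #define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  M[IDX(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = (mode == 1) ? -(go + i * ge) : 0;  // free leading gaps unless global
    tX[IDX(i, 0)] = (i == 1) ? 0 : 1;
    if (mode != 1) { M[IDX(i, 0)] = NEG_INF; }
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = (mode == 1) ? -(go + j * ge) : 0;
    tY[IDX(0, j)] = (j == 1) ? 0 : 1;
  }
  if (mode != 1) { // overlap/local: starting fresh at any (i,0)/(0,j) handled via X/Y=0 + M start
    for (int i = 0; i <= n; ++i) M[IDX(i, 0)] = 0;
    for (int j = 0; j <= m; ++j) M[IDX(0, j)] = 0;
  }

  double best = (mode == 0) ? 0 : NEG_INF;
  int bi_ = n, bj_ = m; char bstate = 'M';

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double sc = use_pssm ? pssm(i - 1, b[j - 1]) : S(a[i - 1], b[j - 1]);
      // M
      double dM = M[IDX(i - 1, j - 1)], dX = X[IDX(i - 1, j - 1)],
             dY = Y[IDX(i - 1, j - 1)];
      double mbest = dM; uint8_t mtb = 0;
      if (dX > mbest) { mbest = dX; mtb = 1; }
      if (dY > mbest) { mbest = dY; mtb = 2; }
      if (mode == 0 && 0.0 > mbest) { mbest = 0.0; mtb = 3; }
      M[IDX(i, j)] = mbest + sc; tM[IDX(i, j)] = mtb;
      if (mode == 0 && M[IDX(i, j)] < 0) { M[IDX(i, j)] = NEG_INF; }
      // X: gap in b (consume a, vertical)
      double xm = M[IDX(i - 1, j)] - (go + ge), xx = X[IDX(i - 1, j)] - ge;
      if (xm >= xx) { X[IDX(i, j)] = xm; tX[IDX(i, j)] = 0; }
      else          { X[IDX(i, j)] = xx; tX[IDX(i, j)] = 1; }
      // Y: gap in a (consume b, horizontal)
      double ym = M[IDX(i, j - 1)] - (go + ge), yy = Y[IDX(i, j - 1)] - ge;
      if (ym >= yy) { Y[IDX(i, j)] = ym; tY[IDX(i, j)] = 0; }
      else          { Y[IDX(i, j)] = yy; tY[IDX(i, j)] = 1; }
      if (mode == 0 && M[IDX(i, j)] > best) {
        best = M[IDX(i, j)]; bi_ = i; bj_ = j; bstate = 'M';
      }
    }
  }

  if (mode == 1) {
    double cand[3] = { M[IDX(n, m)], X[IDX(n, m)], Y[IDX(n, m)] };
    best = cand[0]; bstate = 'M';
    if (cand[1] > best) { best = cand[1]; bstate = 'X'; }
    if (cand[2] > best) { best = cand[2]; bstate = 'Y'; }
    bi_ = n; bj_ = m;
  } else if (mode == 2) {
    best = NEG_INF;
    for (int i = 0; i <= n; ++i)
      if (M[IDX(i, m)] > best) { best = M[IDX(i, m)]; bi_ = i; bj_ = m; bstate = 'M'; }
    for (int j = 0; j <= m; ++j)
      if (M[IDX(n, j)] > best) { best = M[IDX(n, j)]; bi_ = n; bj_ = j; bstate = 'M'; }
    if (best <= NEG_INF / 2) { best = 0; bi_ = 0; bj_ = 0; } // no match state reachable
  }

  res.score = (mode == 0 && best < 0) ? 0 : best;
  if (mode == 0 && best <= 0) return res;  // empty local alignment

  // traceback
  std::vector<int> rai, rbi;
  int i = bi_, j = bj_; char st = bstate;
  while (i > 0 || j > 0) {
    if (st == 'M') {
      if (i == 0 || j == 0) break;           // overlap/local start edge
      uint8_t tb = tM[IDX(i, j)];
      rai.push_back(i - 1); rbi.push_back(j - 1);
      --i; --j;
      if (tb == 3) break;                    // local start
      st = (tb == 0) ? 'M' : (tb == 1 ? 'X' : 'Y');
      if ((mode != 1) && (i == 0 || j == 0) && st == 'M' &&
          M[IDX(i, j)] == 0.0 && (i == 0 || j == 0)) break;
    } else if (st == 'X') {
      if (i == 0) break;
      uint8_t tb = tX[IDX(i, j)];
      if (mode != 1 && j == 0) break;        // free leading gap
      rai.push_back(i - 1); rbi.push_back(-1);
      --i; st = (tb == 0) ? 'M' : 'X';
    } else {
      if (j == 0) break;
      uint8_t tb = tY[IDX(i, j)];
      if (mode != 1 && i == 0) break;
      rai.push_back(-1); rbi.push_back(j - 1);
      --j; st = (tb == 0) ? 'M' : 'Y';
    }
  }
  res.ai.assign(rai.rbegin(), rai.rend());
  res.bi.assign(rbi.rbegin(), rbi.rend());
  int amin = n, amax = -1, bmin = m, bmax = -1;
  for (size_t k = 0; k < res.ai.size(); ++k) {
    if (res.ai[k] >= 0) { if (res.ai[k] < amin) amin = res.ai[k];
                          if (res.ai[k] > amax) amax = res.ai[k]; }
    if (res.bi[k] >= 0) { if (res.bi[k] < bmin) bmin = res.bi[k];
                          if (res.bi[k] > bmax) bmax = res.bi[k]; }
  }
  res.a_start = (amax < 0) ? 0 : amin; res.a_end = amax + 1;
  res.b_start = (bmax < 0) ? 0 : bmin; res.b_end = bmax + 1;
  return res;
  #undef IDX
}

static List wrap_result(const AlnResult& r, const IntegerVector& a,
                        const IntegerVector& b, bool use_pssm) {
  int matches = 0, cols = (int)r.ai.size();
  for (int k = 0; k < cols; ++k)
    if (r.ai[k] >= 0 && r.bi[k] >= 0 && !use_pssm && a[r.ai[k]] == b[r.bi[k]])
      ++matches;
  double ident = (cols > 0 && !use_pssm) ? (double)matches / cols : NA_REAL;
  return List::create(
    _["score"] = r.score,
    _["a_start"] = r.a_start, _["a_end"] = r.a_end,
    _["b_start"] = r.b_start, _["b_end"] = r.b_end,
    _["ai"] = IntegerVector(r.ai.begin(), r.ai.end()),
    _["bi"] = IntegerVector(r.bi.begin(), r.bi.end()),
    _["matches"] = matches, _["columns"] = cols, _["identity"] = ident);
}

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend, int mode) {
  NumericMatrix dummy(0, 0);
  AlnResult r = gotoh(a, b, S, dummy, false, gap_open, gap_extend, mode);
  return wrap_result(r, a, b, false);
}

// [[Rcpp::export]]
List pssm_align_cpp(NumericMatrix pssm, IntegerVector b,
                    double gap_open, double gap_extend) {
  IntegerVector a(pssm.nrow());
  NumericMatrix dummy(0, 0);
  AlnResult r = gotoh(a, b, dummy, pssm, true, gap_open, gap_extend, 0);
  return wrap_result(r, a, b, true);
}

// Score-only local PSSM search against many sequences (O(m) memory),
// used for E-value calibration and round scoring.
// [[Rcpp::export]]
NumericVector pssm_best_scores_cpp(NumericMatrix pssm, List seqs,
                                   double gap_open, double gap_extend) {
  const int n = pssm.nrow();
  NumericVector out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    IntegerVector b = seqs[s];
    const int m = b.size();
    std::vector<double> Mp(m + 1, 0), Xp(m + 1, 0), Yp(m + 1, NEG_INF);
    std::vector<double> Mc(m + 1, 0), Xc(m + 1, 0), Yc(m + 1, NEG_INF);
    double best = 0;
    for (int i = 1; i <= n; ++i) {
      Mc[0] = 0; Xc[0] = 0; Yc[0] = NEG_INF;
      for (int j = 1; j <= m; ++j) {
        double sc = pssm(i - 1, b[j - 1]);
        double dbest = std::max(std::max(Mp[j - 1], Xp[j - 1]),
                                std::max(Yp[j - 1], 0.0));
        double mv = dbest + sc; if (mv < 0) mv = NEG_INF;
        Mc[j] = mv;
        Xc[j] = std::max(Mp[j] - (gap_open + gap_extend), Xp[j] - gap_extend);
        Yc[j] = std::max(Mc[j - 1] - (gap_open + gap_extend), Yc[j - 1] - gap_extend);
        if (Mc[j] > best) best = Mc[j];
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    out[s] = best;
  }
  return out;
}
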