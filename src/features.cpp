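#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- wedge-model helical path ----------------------------------------------

static void rot_z(double ang, double R[3][3]) {
  double c = std::cos(ang), s = std::sin(ang);
  double t[3][3] = {{c, -s, 0}, {s, c, 0}, {0, 0, 1}};
  std::copy(&t[0][0], &t[0][0] + 9, &R[0][0]);
}
static void rot_y(double ang, double R[3][3]) {
  double c = std::cos(ang), s = std::sin(ang);
  double t[3][3] = {{c, 0, s}, {0, 1, 0}, {-s, 0, c}};
  std::copy(&t[0][0], &t[0][0] + 9, &R[0][0]);
}
static void rot_x(double ang, double R[3][3]) {
  double c = std::cos(ang), s = std::sin(ang);
  double t[3][3] = {{1, 0, 0}, {0, c, -s}, {0, s, c}};
  std::copy(&t[0][0], &t[0][0] + 9, &R[0][0]);
}
static void matmul(const double A[3][3], const double B[3][3], double C[3][3]) {
  double t[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      t[i][j] = 0;
      for (int k = 0; k < 3; ++k) t[i][j] += A[i][k] * B[k][j];
    }
  std::copy(&t[0][0], &t[0][0] + 9, &C[0][0]);
}

// seq_code: 0=A,1=C,2=G,3=T, -1 = unknown (N). Dinucleotide index = 4*first+second.
// twist/roll/tilt: length-16 vectors in degrees. Unknown steps get zero wedge
// and the mean twist. Returns (L-1) x 3 axis points, unit spacing, plus the
// number of unknown steps as attribute "n_unknown".
// [[Rcpp::export]]
NumericMatrix helical_path_cpp(IntegerVector seq_code, NumericVector twist,
                               NumericVector roll, NumericVector tilt) {
  const int L = seq_code.size();
  if (L < 2) stop("sequence must have length >= 2");
  const double d2r = M_PI / 180.0;
  double mean_twist = 0;
  for (int k = 0; k < 16; ++k) mean_twist += twist[k];
  mean_twist /= 16.0;

  NumericMatrix out(L - 1, 3);
  double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double px = 0, py = 0, pz = 0;
  int n_unknown = 0;
  double Rz[3][3], Ry[3][3], Rx[3][3];
  for (int i = 0; i < L - 1; ++i) {
    int a = seq_code[i], b = seq_code[i + 1];
    double tw, ro, ti;
    if (a < 0 || b < 0) { tw = mean_twist; ro = 0; ti = 0; ++n_unknown; }
    else {
      int d = 4 * a + b;
      tw = twist[d]; ro = roll[d]; ti = tilt[d];
    }
    rot_z(tw * d2r, Rz); rot_y(ro * d2r, Ry); rot_x(ti * d2r, Rx);
    matmul(F, Rz, F); matmul(F, Ry, F); matmul(F, Rx, F);
    // advance one unit along the local helix axis
    px += F[0][2]; py += F[1][2]; pz += F[2][2];
    out(i, 0) = px; out(i, 1) = py; out(i, 2) = pz;
  }
  out.attr("n_unknown") = n_unknown;
  return out;
}

// ---- repeat / palindrome finder --------------------------------------------

// Maximal runs along a diagonal at every mismatch level 0..k, with edge
// mismatches trimmed, deduplicated. A hit that is maximal at its own
// mismatch count is reported even when a longer, noisier window exists.
// Positions of mismatches along a diagonal of length len are in `mm`.
// Emits [start, end) windows (0-based along the diagonal).
static void maximal_windows(const std::vector<int>& mm, int len, int kmax,
                            std::vector<std::pair<int, int> >& out) {
  std::vector<int> b;           // boundaries: -1, mismatches, len
  b.push_back(-1);
  b.insert(b.end(), mm.begin(), mm.end());
  b.push_back(len);
  int nb = (int)b.size();
  for (int k = 0; k <= kmax; ++k) {
    for (int t = 0; t + k + 1 < nb; ++t) {
      int lo = b[t] + 1, hi = b[t + k + 1]; // window [lo, hi), contains <= k mm
      if (hi - lo <= 0) continue;
      // trim mismatches at the edges
      int s = t + 1, e = t + k;             // indices of mismatches inside
      int lo2 = lo, hi2 = hi;
      while (s <= e && b[s] == lo2) { ++lo2; ++s; }
      while (e >= s && b[e] == hi2 - 1) { --hi2; --e; }
      if (hi2 - lo2 > 0) out.push_back(std::make_pair(lo2, hi2));
    }
  }
  // dedupe identical windows after trimming
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

static inline bool is_comp(int a, int b) {      // 0=A,1=C,2=G,3=T
  return (a >= 0 && b >= 0 && a + b == 3);
}

// Exhaustive direct / inverted repeat / palindrome scan.
// Returns a data.frame-able list with 1-based arm positions.
// [[Rcpp::export]]
List find_repeats_cpp(IntegerVector s, int min_arm, int max_loop,
                      int max_mismatch) {
  const int n = s.size();
  std::vector<std::string> kind;
  std::vector<int> a1, a2, armlen, looplen, nmm;

  // direct repeats: diagonal offset d = j - i >= 1
  for (int d = 1; d < n; ++d) {
    int len = n - d;
    if (len < min_arm) break;
    std::vector<int> mm;
    for (int p = 0; p < len; ++p)
      if (s[p] < 0 || s[p + d] < 0 || s[p] != s[p + d]) mm.push_back(p);
    std::vector<std::pair<int, int> > wins;
    maximal_windows(mm, len, max_mismatch, wins);
    for (size_t t = 0; t < wins.size(); ++t) {
      int lo = wins[t].first, hi = wins[t].second, arm = hi - lo;
      if (arm < min_arm) continue;
      if (d < arm) continue;                 // arms must not overlap
      int c = 0;
      for (int p = lo; p < hi; ++p)
        if (s[p] < 0 || s[p + d] < 0 || s[p] != s[p + d]) ++c;
      kind.push_back("direct");
      a1.push_back(lo + 1); a2.push_back(lo + d + 1);
      armlen.push_back(arm); looplen.push_back(d - arm); nmm.push_back(c);
    }
  }

  // inverted repeats / palindromes: anti-diagonal C = p + q (pairs p < q)
  for (int C = 1; C <= 2 * n - 3; ++C) {
    // paired positions (p, C - p), p from 0 up to floor((C-1)/2)
    int pmax = (C - 1) / 2;
    int pmin = std::max(0, C - (n - 1));
    int len = pmax - pmin + 1;
    if (len < min_arm) continue;
    std::vector<int> mm;
    for (int p = pmin; p <= pmax; ++p)
      if (!is_comp(s[p], s[C - p])) mm.push_back(p - pmin);
    std::vector<std::pair<int, int> > wins;
    maximal_windows(mm, len, max_mismatch, wins);
    for (size_t t = 0; t < wins.size(); ++t) {
      int lo = wins[t].first, hi = wins[t].second, arm = hi - lo;
      if (arm < min_arm) continue;
      int p_in = pmin + hi - 1;              // innermost pair
      int loop = C - 2 * p_in - 1;
      if (loop < 0 || loop > max_loop) continue;
      int p_out = pmin + lo;
      int c = 0;
      for (int p = p_out; p <= p_in; ++p)
        if (!is_comp(s[p], s[C - p])) ++c;
      kind.push_back(loop == 0 ? "palindrome" : "inverted");
      a1.push_back(p_out + 1); a2.push_back(C - p_in + 1);
      armlen.push_back(arm); looplen.push_back(loop); nmm.push_back(c);
    }
  }

  return List::create(_["kind"] = kind, _["arm1_start"] = a1,
                      _["arm2_start"] = a2, _["arm_len"] = armlen,
                      _["loop_len"] = looplen, _["mismatches"] = nmm);
}
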