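#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One ZOOPS (zero-or-one occurrence per sequence) EM fit at fixed width.
// seqs: integer vectors over 0..K-1; pwm0: w x K initial probabilities;
// bg: K background frequencies. Returns fitted pwm, gamma, log-likelihood,
// per-sequence best offset (0-based, -1 if none scores) and site posterior.
// [[Rcpp::export]]
List zoops_em_cpp(List seqs, NumericMatrix pwm0, NumericVector bg,
                  double gamma0, int max_iter, double tol, double pseudo) {
  const int n = seqs.size(), w = pwm0.nrow(), K = pwm0.ncol();
  std::vector<std::vector<int> > S(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    S[i].assign(v.begin(), v.end());
  }
  NumericMatrix pwm = clone(pwm0);
  double gamma = gamma0, ll_old = -1e300, ll = 0;

  std::vector<double> logbg(K);
  for (int a = 0; a < K; ++a) logbg[a] = std::log(bg[a]);

  NumericMatrix counts(w, K);
  std::vector<double> zsum(n, 0.0);
  std::vector<int> bestpos(n, -1);
  std::vector<double> bestz(n, 0.0);

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(counts.begin(), counts.end(), 0.0);
    ll = 0;
    std::vector<std::vector<double> > Z(n);
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& s = S[i];
      int m = (int)s.size() - w + 1;
      if (m <= 0) { zsum[i] = 0; bestpos[i] = -1; ll += 0; continue; }
      std::vector<double> lr(m);
      double sumLR = 0;
      for (int j = 0; j < m; ++j) {
        double lg = 0;
        for (int k = 0; k < w; ++k) {
          int a = s[j + k];
          lg += std::log(pwm(k, a)) - logbg[a];
        }
        lr[j] = std::exp(lg);
        sumLR += lr[j];
      }
      double denom = (1.0 - gamma) + (gamma / m) * sumLR;
      ll += std::log(denom);
      Z[i].resize(m);
      double zs = 0; int bp = -1; double bz = -1;
      for (int j = 0; j < m; ++j) {
        double z = (gamma / m) * lr[j] / denom;
        Z[i][j] = z; zs += z;
        if (z > bz) { bz = z; bp = j; }
      }
      zsum[i] = zs; bestpos[i] = bp; bestz[i] = bz;
      for (int j = 0; j < m; ++j) {
        double z = Z[i][j];
        if (z < 1e-12) continue;
        for (int k = 0; k < w; ++k) counts(k, s[j + k]) += z;
      }
    }
    // M-step
    for (int k = 0; k < w; ++k) {
      double tot = 0;
      for (int a = 0; a < K; ++a) tot += counts(k, a) + pseudo * bg[a];
      for (int a = 0; a < K; ++a)
        pwm(k, a) = (counts(k, a) + pseudo * bg[a]) / tot;
    }
    double gz = 0; int nn = 0;
    for (int i = 0; i < n; ++i) { gz += zsum[i]; ++nn; }
    gamma = std::min(0.999, std::max(1e-6, gz / std::max(1, nn)));
    if (std::fabs(ll - ll_old) < tol) break;
    ll_old = ll;
  }
  return List::create(_["pwm"] = pwm, _["gamma"] = gamma, _["loglik"] = ll,
                      _["best_pos"] = IntegerVector(bestpos.begin(), bestpos.end()),
                      _["site_post"] = NumericVector(zsum.begin(), zsum.end()));
}

// Best log-odds window score and its position per sequence.
// logodds: w x K matrix. Returns n x 2 (score, 0-based position; NA if short).
// [[Rcpp::export]]
NumericMatrix pwm_best_hit_cpp(NumericMatrix logodds, List seqs) {
  const int w = logodds.nrow();
  NumericMatrix out(seqs.size(), 2);
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector s = seqs[i];
    int m = s.size() - w + 1;
    if (m <= 0) { out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; continue; }
    double best = -1e300; int bp = 0;
    for (int j = 0; j < m; ++j) {
      double sc = 0;
      for (int k = 0; k < w; ++k) sc += logodds(k, s[j + k]);
      if (sc > best) { best = sc; bp = j; }
    }
    out(i, 0) = best; out(i, 1) = bp;
  }
  return out;
}
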