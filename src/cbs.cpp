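#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Max circular-arc statistic for one segment of values.
//
// For an arc (i, j] on the circularized sequence (0 <= i < j <= n, arc
// length k = j - i), the statistic is the mean-difference t-like contrast
//   |mean_in - mean_out| / sqrt(1/k + 1/(n-k)).
// The residual scale is constant over arcs and over permutations of the
// same values, so it cancels and is omitted. Arcs must leave both the in-
// and out-arc parts with at least min_width points; for interior arcs
// (ternary splits) both linear edge pieces must also have at least
// min_width points. Ties are broken toward the smallest i, then smallest j
// (strict > comparison keeps the first maximum encountered).
static void scan_best(const std::vector<double> &S, int n, int min_width,
                      double *best, int *bi, int *bj) {
  const double tot = S[n];
  double b = -1.0;
  int ii = -1, jj = -1;
  for (int i = 0; i <= n - 1; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      const int k = j - i;
      if (k < min_width || n - k < min_width) continue;
      if (i > 0 && j < n && (i < min_width || n - j < min_width)) continue;
      const double sin_ = S[j] - S[i];
      const double d = sin_ / k - (tot - sin_) / (n - k);
      const double st = std::fabs(d) / std::sqrt(1.0 / k + 1.0 / (n - k));
      if (st > b) { b = st; ii = i; jj = j; }
    }
  }
  *best = b; *bi = ii; *bj = jj;
}

// [[Rcpp::export]]
List cbs_scan(NumericVector x, int min_width) {
  const int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  double best; int bi, bj;
  scan_best(S, n, min_width, &best, &bi, &bj);
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Max arc statistics of nperm random permutations of x, using R's RNG
// (deterministic under set.seed on any platform).
// [[Rcpp::export]]
NumericVector cbs_perm_max(NumericVector x, int nperm, int min_width) {
  RNGScope scope;
  const int n = x.size();
  NumericVector out(nperm);
  std::vector<double> y(x.begin(), x.end());
  std::vector<double> S(n + 1, 0.0);
  for (int p = 0; p < nperm; ++p) {
    for (int t = n - 1; t > 0; --t) {
      int u = static_cast<int>(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(y[t], y[u]);
    }
    for (int t = 0; t < n; ++t) S[t + 1] = S[t] + y[t];
    double best; int bi, bj;
    scan_best(S, n, min_width, &best, &bi, &bj);
    out[p] = best;
  }
  return out;
}
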