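#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static double quantile7(std::vector<double> &buf, double p) {
  const int n = buf.size();
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
  double xlo = buf[lo];
  if (lo + 1 >= n) return xlo;
  double xhi = *std::min_element(buf.begin() + lo + 1, buf.end());
  return xlo + (h - lo) * (xhi - xlo);
}

// Per-row type-7 lower/upper quantiles of a matrix.
// [[Rcpp::export]]
NumericMatrix row_quantiles2(NumericMatrix x, double plo, double phi) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, 2);
  std::vector<double> buf(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) buf[j] = x(i, j);
    out(i, 0) = quantile7(buf, plo);
    for (int j = 0; j < m; ++j) buf[j] = x(i, j);
    out(i, 1) = quantile7(buf, phi);
  }
  return out;
}

// Monte-Carlo equal-tailed quantiles of the difference of two beta
// posteriors, per site. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
NumericMatrix beta_diff_quantiles(NumericVector a1, NumericVector b1,
                                  NumericVector a2, NumericVector b2,
                                  int n_draws, double plo, double phi) {
  const int n = a1.size();
  NumericMatrix out(n, 2);
  std::vector<double> buf(n_draws), buf2(n_draws);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n_draws; ++j) {
      buf[j] = R::rbeta(a2[i], b2[i]) - R::rbeta(a1[i], b1[i]);
    }
    buf2 = buf;
    out(i, 0) = quantile7(buf2, plo);
    buf2 = buf;
    out(i, 1) = quantile7(buf2, phi);
  }
  return out;
}
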