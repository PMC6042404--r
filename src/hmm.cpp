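#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a two-state HMM with precomputed emission
// likelihoods. Returns posterior state probabilities, summed expected
// transition counts, expected initial-state occupancy and the log-likelihood.
// [[Rcpp::export]]
List fb_two_state(NumericMatrix emis, NumericMatrix trans, NumericVector pi) {
  const int n = emis.nrow();
  NumericMatrix alpha(n, 2), beta(n, 2), gamma(n, 2);
  NumericVector scale(n);
  double loglik = 0.0;

  alpha(0, 0) = pi[0] * emis(0, 0);
  alpha(0, 1) = pi[1] * emis(0, 1);
  scale[0] = alpha(0, 0) + alpha(0, 1);
  if (scale[0] <= 0) scale[0] = 1e-300;
  alpha(0, 0) /= scale[0];
  alpha(0, 1) /= scale[0];
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < 2; ++j) {
      alpha(t, j) = (alpha(t - 1, 0) * trans(0, j) +
                     alpha(t - 1, 1) * trans(1, j)) * emis(t, j);
    }
    scale[t] = alpha(t, 0) + alpha(t, 1);
    if (scale[t] <= 0) scale[t] = 1e-300;
    alpha(t, 0) /= scale[t];
    alpha(t, 1) /= scale[t];
  }
  for (int t = 0; t < n; ++t) loglik += std::log(scale[t]);

  beta(n - 1, 0) = 1.0;
  beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < 2; ++i) {
      beta(t, i) = (trans(i, 0) * emis(t + 1, 0) * beta(t + 1, 0) +
                    trans(i, 1) * emis(t + 1, 1) * beta(t + 1, 1)) / scale[t + 1];
    }
  }

  for (int t = 0; t < n; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    if (s <= 0) s = 1e-300;
    gamma(t, 0) = g0 / s;
    gamma(t, 1) = g1 / s;
  }

  NumericMatrix xi(2, 2);
  for (int t = 0; t < n - 1; ++t) {
    double denom = 0.0;
    double tmp[2][2];
    for (int i = 0; i < 2; ++i) {
      for (int j = 0; j < 2; ++j) {
        tmp[i][j] = alpha(t, i) * trans(i, j) * emis(t + 1, j) *
                    beta(t + 1, j) / scale[t + 1];
        denom += tmp[i][j];
      }
    }
    if (denom <= 0) denom = 1e-300;
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j) xi(i, j) += tmp[i][j] / denom;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik,
                      _["initial"] = NumericVector::create(gamma(0, 0),
                                                           gamma(0, 1)));
}
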