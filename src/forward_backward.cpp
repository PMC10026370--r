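#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-state HMM.
// logB: T x K log observation densities; P: K x K row-stochastic
// transition matrix; pi0: K initial distribution.
// Returns per-sample posteriors (gamma), summed expected transition
// counts (xi_sum) and the data log-likelihood.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logB, NumericMatrix P, NumericVector pi0) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector cs(T), shift(T);
  double logshift = 0.0;

  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, logB(t, k));
    shift[t] = mx;
    logshift += mx;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - mx);
  }

  double c0 = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = pi0[k] * B(0, k);
    c0 += alpha(0, k);
  }
  cs[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += P(j, k) * alpha(t - 1, j);
      double a = s * B(t, k);
      alpha(t, k) = a;
      ct += a;
    }
    cs[t] = ct;
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j)
        s += P(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = s / cs[t + 1];
    }
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      double m = B(t + 1, j) * beta(t + 1, j) / cs[t + 1];
      for (int i = 0; i < K; ++i)
        xi(i, j) += alpha(t, i) * P(i, j) * m;
    }
  }

  double loglik = logshift;
  for (int t = 0; t < T; ++t) loglik += std::log(cs[t]);
  for (int t = 0; t < T; ++t) {
    double rs = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      rs += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= rs;
  }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["loglik"] = loglik);
}
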