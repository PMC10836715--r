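#include <Rcpp.h>
using namespace Rcpp;

// First-order vector-autoregressive recursion x[,t] = A x[,t-1] + e[,t].
// e is channels x samples and is overwritten conceptually; the result is
// returned as a new matrix. Used by the synthetic-recording generator.
// [[Rcpp::export(name = ".var_filter")]]
NumericMatrix var_filter(NumericMatrix A, NumericMatrix e) {
  const int p = e.nrow(), n = e.ncol();
  NumericMatrix x(p, n);
  for (int i = 0; i < p; ++i) x(i, 0) = e(i, 0);
  for (int t = 1; t < n; ++t) {
    for (int i = 0; i < p; ++i) {
      double acc = e(i, t);
      for (int j = 0; j < p; ++j) acc += A(i, j) * x(j, t - 1);
      x(i, t) = acc;
    }
  }
  return x;
}

// Scaled forward-backward for a hidden Markov chain given per-frame state
// likelihoods B (T x K), initial distribution pi and transition matrix P.
// Returns log-likelihood, posteriors gamma (T x K) and the summed two-slice
// posteriors xi (K x K), the sufficient statistics for the Baum-Welch
// M-step.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(NumericMatrix B, NumericVector pi,
                          NumericMatrix P) {
  const int T = B.nrow(), K = B.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  const double tiny = 1e-300;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = pi[k] * B(0, k);
    s += alpha(0, k);
  }
  if (s < tiny) s = tiny;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * P(j, k);
      alpha(t, k) = acc * B(t, k);
      s += alpha(t, k);
    }
    if (s < tiny) s = tiny;
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j)
        acc += P(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = acc / c[t + 1];
    }
  }

  // posteriors and two-slice sums
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    if (g < tiny) g = tiny;
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        xi(j, k) += alpha(t, j) * P(j, k) * B(t + 1, k) * beta(t + 1, k) /
                    c[t + 1];
      }
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return List::create(_["log_lik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}
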