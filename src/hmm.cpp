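#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward for a K-state HMM with Gaussian emissions.
// Returns log-likelihood, posterior state probabilities (gamma) and the
// summed transition responsibilities (xi) needed for the EM M-step.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector mu, NumericVector sd,
                          NumericMatrix trans, NumericVector init) {
  const int T = x.size();
  const int K = mu.size();
  NumericMatrix emit(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericMatrix xi(K, K);
  NumericVector scale(T);

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (x[t] - mu[k]) / sd[k];
      emit(t, k) = std::exp(-0.5 * z * z) / (sd[k] * 2.5066282746310002);
      if (emit(t, k) < 1e-300) emit(t, k) = 1e-300;
    }

  double c0 = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * emit(0, k); c0 += alpha(0, k); }
  scale[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = s * emit(t, k);
      ct += alpha(t, k);
    }
    scale[t] = ct;
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += trans(k, j) * emit(t + 1, j) * beta(t + 1, j);
      beta(t, k) = s / scale[t + 1];
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    loglik += std::log(scale[t]);
    double gs = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); gs += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= gs;
  }

  for (int t = 0; t < T - 1; ++t) {
    double denom = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        denom += alpha(t, j) * trans(j, k) * emit(t + 1, k) * beta(t + 1, k);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * trans(j, k) * emit(t + 1, k) * beta(t + 1, k) / denom;
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding for the same model; returns the MAP state path (1-based).
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, NumericVector sd,
                          NumericMatrix trans, NumericVector init) {
  const int T = x.size();
  const int K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix ltrans(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      ltrans(j, k) = std::log(trans(j, k) + 1e-300);

  auto lemit = [&](int t, int k) {
    double z = (x[t] - mu[k]) / sd[k];
    return -0.5 * z * z - std::log(sd[k]) - 0.9189385332046727;
  };

  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(init[k] + 1e-300) + lemit(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + ltrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + lemit(t, k);
      psi(t, k) = arg;
    }

  IntegerVector path(T);
  int arg = 0; double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
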