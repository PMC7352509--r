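// Log-space forward-backward recursions for the 3-state Gaussian HMM.
// Emission log-densities are computed in R and passed as a T x K matrix.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_sum_exp3(const double* v, int K) {
  double m = v[0];
  for (int k = 1; k < K; ++k) if (v[k] > m) m = v[k];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::exp(v[k] - m);
  return m + std::log(s);
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericMatrix logB, NumericVector logpi,
                       NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  std::vector<double> alpha(K), prev(K), work(K);
  for (int k = 0; k < K; ++k) alpha[k] = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    prev = alpha;
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) work[j] = prev[j] + logA(j, k);
      alpha[k] = log_sum_exp3(work.data(), K) + logB(t, k);
    }
  }
  return log_sum_exp3(alpha.data(), K);
}

// Forward-backward: returns loglik, state posteriors gamma (T x K) and
// expected transition counts xi summed over t (K x K).
// [[Rcpp::export(name = ".hmm_fwdbwd_cpp")]]
List hmm_fwdbwd_cpp(NumericMatrix logB, NumericVector logpi,
                    NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix la(T, K), lb(T, K), gamma(T, K);
  NumericMatrix xi(K, K);
  std::vector<double> work(K);

  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) work[j] = la(t - 1, j) + logA(j, k);
      la(t, k) = log_sum_exp3(work.data(), K) + logB(t, k);
    }
  }
  std::vector<double> last(K);
  for (int k = 0; k < K; ++k) last[k] = la(T - 1, k);
  const double loglik = log_sum_exp3(last.data(), K);

  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        work[k] = logA(j, k) + logB(t + 1, k) + lb(t + 1, k);
      }
      lb(t, j) = log_sum_exp3(work.data(), K);
    }
  }

  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = std::exp(la(t, k) + lb(t, k) - loglik);
    }
  }
  for (int t = 0; t + 1 < T; ++t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        xi(j, k) += std::exp(la(t, j) + logA(j, k) + logB(t + 1, k) +
                             lb(t + 1, k) - loglik);
      }
    }
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}
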