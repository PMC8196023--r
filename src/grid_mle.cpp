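#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Phi(b) - Phi(a), a < b, via erf/erfc with tail mirroring so the
// difference never cancels catastrophically
static inline double phi_diff(double a, double b) {
  if (a > 0.0) { double t = a; a = -b; b = -t; } // mirror into lower tail
  if (b <= 0.0) {
    // both bounds in lower tail: difference of small erfc terms
    return 0.5 * (erfc(-b * M_SQRT1_2) - erfc(-a * M_SQRT1_2));
  }
  return 0.5 * (erf(b * M_SQRT1_2) - erf(a * M_SQRT1_2));
}

// Exhaustive grid maximization of the interval-censored normal
// log-likelihood over (mu, log sigma). Point "intervals" (lower == upper)
// contribute the normal density. Returns c(mu, log_sigma, loglik).
// [[Rcpp::export]]
NumericVector cpp_grid_interval_mle(NumericVector lower, NumericVector upper,
                                    double mu_min, double mu_max,
                                    double ls_min, double ls_max,
                                    double step) {
  const int n = lower.size();
  const int n_mu = (int)std::floor((mu_max - mu_min) / step + 0.5) + 1;
  const int n_ls = (int)std::floor((ls_max - ls_min) / step + 0.5) + 1;
  double best_ll = R_NegInf, best_mu = mu_min, best_ls = ls_min;
  for (int s = 0; s < n_ls; ++s) {
    const double ls = ls_min + s * step;
    const double sigma = std::exp(ls);
    const double inv_sigma = 1.0 / sigma;
    for (int m = 0; m < n_mu; ++m) {
      const double mu = mu_min + m * step;
      // accumulate the likelihood as a product; one log at the end
      // (underflow to 0 maps to -Inf, only in hopeless regions)
      double lik = 1.0;
      double ll_exact = 0.0;
      for (int i = 0; i < n; ++i) {
        if (lower[i] == upper[i]) {
          ll_exact += R::dnorm(lower[i], mu, sigma, 1);
        } else {
          lik *= phi_diff((lower[i] - mu) * inv_sigma,
                          (upper[i] - mu) * inv_sigma);
        }
      }
      const double ll = (lik > 0.0 ? std::log(lik) : R_NegInf) + ll_exact;
      if (ll > best_ll) { best_ll = ll; best_mu = mu; best_ls = ls; }
    }
  }
  return NumericVector::create(best_mu, best_ls, best_ll);
}
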