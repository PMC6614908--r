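#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spike-and-slab (Bayesian variable selection) Gibbs sampler on the
// sufficient statistics of a linear model with standardized inputs:
//   y = X beta + e,  e ~ N(0, sigma2 I)
//   beta_j = gamma_j b_j,  b_j ~ N(0, sb2 * sigma2)
//   gamma_j ~ Bernoulli(pi),  pi ~ Beta(pi_a, pi_b)
//   sigma2 ~ 1/sigma2 (reference),  sb2 ~ InvGamma(sb2_a, sb2_b)
// At every `thin`-th post-burn-in iteration the included site with the
// largest |beta| is counted as the predicted causal variant.
// Uses R's RNG, so set.seed() in R makes runs reproducible.
// [[Rcpp::export]]
List spike_slab_gibbs(const NumericMatrix& XtX, const NumericVector& Xty,
                      double yty, int n, int n_iter, int burn_in, int thin,
                      double pi_a, double pi_b, double sb2_a, double sb2_b) {
  const int M = XtX.ncol();
  std::vector<double> beta(M, 0.0), v(M, 0.0);  // v = XtX %*% beta
  std::vector<int> gamma(M, 0);
  IntegerVector counts(M);
  double sigma2 = yty / n;
  double sb2 = 0.1;
  double pi = 1.0 / std::max(M, 2);
  int n_counted = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < M; ++j) {
      const double xtx = XtX(j, j);
      if (xtx <= 0.0) continue;
      const double rj = Xty[j] - (v[j] - xtx * beta[j]);
      const double prec = xtx + 1.0 / sb2;
      const double mj = rj / prec;
      double logodds = std::log(pi) - std::log1p(-pi)
        + 0.5 * (std::log(1.0 / sb2) - std::log(prec))
        + rj * rj / (2.0 * sigma2 * prec);
      if (logodds > 35.0) logodds = 35.0;
      const double pincl = 1.0 / (1.0 + std::exp(-logodds));
      const double old = beta[j];
      int g = (R::unif_rand() < pincl) ? 1 : 0;
      double b = 0.0;
      if (g) b = R::rnorm(mj, std::sqrt(sigma2 / prec));
      gamma[j] = g;
      beta[j] = b;
      const double d = b - old;
      if (d != 0.0) for (int h = 0; h < M; ++h) v[h] += XtX(h, j) * d;
    }
    double btv = 0.0, btXty = 0.0, ssb = 0.0;
    int k = 0;
    for (int j = 0; j < M; ++j) {
      btv += beta[j] * v[j];
      btXty += beta[j] * Xty[j];
      ssb += beta[j] * beta[j];
      if (gamma[j]) ++k;
    }
    double sse = yty - 2.0 * btXty + btv;
    if (sse < 1e-12) sse = 1e-12;
    sigma2 = 1.0 / R::rgamma(0.5 * (n + k),
                             1.0 / (0.5 * (sse + ssb / sb2)));
    sb2 = 1.0 / R::rgamma(sb2_a + 0.5 * k,
                          1.0 / (sb2_b + 0.5 * ssb / sigma2));
    if (sb2 < 1e-8) sb2 = 1e-8;
    pi = R::rbeta(pi_a + k, pi_b + (M - k));
    if (pi < 1e-12) pi = 1e-12;
    if (pi > 1.0 - 1e-12) pi = 1.0 - 1e-12;

    if (it >= burn_in && (it - burn_in) % thin == thin - 1) {
      int best = -1;
      double bb = -1.0;
      for (int j = 0; j < M; ++j) {
        if (gamma[j] && std::fabs(beta[j]) > bb) {
          bb = std::fabs(beta[j]);
          best = j;
        }
      }
      if (best >= 0) counts[best]++;
      ++n_counted;
    }
  }
  return List::create(_["counts"] = counts, _["n_counted"] = n_counted);
}
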