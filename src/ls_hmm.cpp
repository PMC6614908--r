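#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Li-Stephens haplotype-copying HMM: posterior P(allele = 1) at every
// reference site for each target haplotype, by scaled forward-backward.
// Hidden state = reference haplotype copied; transitions switch to a
// uniformly chosen reference haplotype with probability rho[j] between
// sites j and j+1; emissions apply only at observed (array) sites with
// per-allele error `mismatch`.
//
// ref:       H x M reference alleles (0/1)
// obs:       T x K target-haplotype alleles at the K array sites
// array_idx: K 1-based column indices of the array sites within ref
// rho:       M-1 switch probabilities
// [[Rcpp::export]]
NumericMatrix ls_posterior_allele(const IntegerMatrix& ref,
                                  const IntegerMatrix& obs,
                                  const IntegerVector& array_idx,
                                  const NumericVector& rho,
                                  double mismatch) {
  const int H = ref.nrow(), M = ref.ncol(), T = obs.nrow();
  const int K = array_idx.size();
  if (M > 1 && rho.size() != M - 1) stop("rho must have length M - 1");

  std::vector<int> ocol(M, -1);
  for (int k = 0; k < K; ++k) {
    int j = array_idx[k] - 1;
    if (j < 0 || j >= M) stop("array_idx out of range");
    ocol[j] = k;
  }

  NumericMatrix out(T, M);
  std::vector<double> fwd(static_cast<size_t>(H) * M);
  std::vector<double> beta(H), tmp(H), csc(M);

  for (int t = 0; t < T; ++t) {
    // forward
    for (int j = 0; j < M; ++j) {
      double* fj = &fwd[static_cast<size_t>(j) * H];
      if (j == 0) {
        for (int h = 0; h < H; ++h) fj[h] = 1.0 / H;
      } else {
        const double* fp = &fwd[static_cast<size_t>(j - 1) * H];
        double s = 0.0;
        for (int h = 0; h < H; ++h) s += fp[h];
        const double stay = 1.0 - rho[j - 1];
        const double sw = rho[j - 1] * s / H;
        for (int h = 0; h < H; ++h) fj[h] = stay * fp[h] + sw;
      }
      if (ocol[j] >= 0) {
        const int a = obs(t, ocol[j]);
        for (int h = 0; h < H; ++h)
          fj[h] *= (ref(h, j) == a) ? (1.0 - mismatch) : mismatch;
      }
      double c = 0.0;
      for (int h = 0; h < H; ++h) c += fj[h];
      if (c <= 0.0) {  // numerically dead: reset to uniform
        for (int h = 0; h < H; ++h) fj[h] = 1.0 / H;
        c = 1.0;
      }
      csc[j] = c;
      for (int h = 0; h < H; ++h) fj[h] /= c;
    }
    // backward + posterior allele probability
    for (int h = 0; h < H; ++h) beta[h] = 1.0;
    for (int j = M - 1; j >= 0; --j) {
      const double* fj = &fwd[static_cast<size_t>(j) * H];
      double norm = 0.0, pa = 0.0;
      for (int h = 0; h < H; ++h) {
        const double g = fj[h] * beta[h];
        norm += g;
        if (ref(h, j) == 1) pa += g;
      }
      out(t, j) = (norm > 0.0) ? pa / norm : 0.5;
      if (j > 0) {
        double s = 0.0;
        const int k = ocol[j];
        for (int h = 0; h < H; ++h) {
          double e = 1.0;
          if (k >= 0) {
            const int a = obs(t, k);
            e = (ref(h, j) == a) ? (1.0 - mismatch) : mismatch;
          }
          tmp[h] = e * beta[h];
          s += tmp[h];
        }
        const double stay = 1.0 - rho[j - 1];
        const double sw = rho[j - 1] / H;
        const double c = csc[j];
        for (int h = 0; h < H; ++h) beta[h] = (stay * tmp[h] + sw * s) / c;
      }
    }
  }
  return out;
}
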