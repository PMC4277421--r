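#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Permutation engine for the adaptive combination test.
//
// For each of B permutations: regenerate non-founder haplotypes by gene
// dropping (one haplotype drawn from each parent's current pair, founders
// fixed), then accumulate the per-threshold significance scores
//   S_j = sum_l (-log P_l) * 1[P_l < theta_j]
// over valid sites, where P_l is the upper chi^2_1 tail of
//   T_l = (r' g_l)^2 / (2 p_l (1 - p_l) r'Phi r).
//
// The founder contribution to r'g_l and the denominator factors are
// genotype-invariant under the permutation null and are precomputed.
// Haplotypes are held row-major (one contiguous block per individual) so
// a meiosis is a memcpy and the score accumulation streams memory.
// Uniform deviates are supplied by the caller (drawn from R's RNG), two
// per non-founder per permutation, in founders-first order: this keeps
// the stream identical to the R reference path (gene_drop +
// site_statistics).

// [[Rcpp::export]]
NumericMatrix perm_scores_cpp(const IntegerMatrix& h1,
                              const IntegerMatrix& h2,
                              const IntegerVector& fa,
                              const IntegerVector& mo,
                              const IntegerVector& nonf,
                              const NumericVector& r,
                              const double denom,
                              const NumericVector& p,
                              const LogicalVector& valid,
                              const NumericVector& thresholds,
                              const NumericMatrix& U,
                              const int log10_transform) {
  const int n = h1.nrow(), L = h1.ncol();
  const int K = nonf.size();
  const int B = U.ncol();
  const int J = thresholds.size();
  if (U.nrow() != 2 * K) stop("U must have 2 * K rows");

  // row-major working copies: individual i's haplotype = W[i*L .. i*L+L-1]
  std::vector<int> W1((size_t)n * L), W2((size_t)n * L);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      W1[(size_t)i * L + l] = h1(i, l);
      W2[(size_t)i * L + l] = h2(i, l);
    }

  // founder part of r' g_l
  std::vector<char> isf(n, 1);
  for (int k = 0; k < K; ++k) isf[nonf[k]] = 0;
  std::vector<double> base(L, 0.0);
  for (int i = 0; i < n; ++i) {
    if (!isf[i]) continue;
    const double ri = r[i];
    const int* a = &W1[(size_t)i * L];
    const int* b = &W2[(size_t)i * L];
    for (int l = 0; l < L; ++l) base[l] += ri * (a[l] + b[l]);
  }
  std::vector<double> dfac(L, 1.0);
  for (int l = 0; l < L; ++l)
    if (valid[l]) dfac[l] = 2.0 * p[l] * (1.0 - p[l]) * denom;

  const double ln10 = std::log(10.0);
  const size_t bytes = (size_t)L * sizeof(int);
  std::vector<double> s(L);
  NumericMatrix S(B, J);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < K; ++k) {
      const int i = nonf[k], f = fa[i], m = mo[i];
      const int* srcf = (U(2 * k, b) < 0.5 ? W1 : W2).data() + (size_t)f * L;
      const int* srcm = (U(2 * k + 1, b) < 0.5 ? W1 : W2).data() + (size_t)m * L;
      std::memcpy(&W1[(size_t)i * L], srcf, bytes);
      std::memcpy(&W2[(size_t)i * L], srcm, bytes);
    }
    std::copy(base.begin(), base.end(), s.begin());
    for (int k = 0; k < K; ++k) {
      const int i = nonf[k];
      const double ri = r[i];
      const int* a = &W1[(size_t)i * L];
      const int* bb = &W2[(size_t)i * L];
      for (int l = 0; l < L; ++l) s[l] += ri * (a[l] + bb[l]);
    }
    for (int l = 0; l < L; ++l) {
      if (!valid[l]) continue;
      const double T = s[l] * s[l] / dfac[l];
      const double pv = R::pchisq(T, 1.0, 0, 0);
      double w = -std::log(pv);
      if (log10_transform) w /= ln10;
      for (int j = J - 1; j >= 0; --j) {
        if (pv < thresholds[j]) S(b, j) += w; else break;
      }
    }
  }
  return S;
}
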