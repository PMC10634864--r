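#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// R-squared of every non-empty predictor subset from sufficient statistics.
// Rxx is the p x p predictor correlation matrix and rxy the predictor-response
// correlations (standardised data), so R2(S) = r_S' Rxx[S,S]^{-1} r_S.
// Result is indexed by bitmask (entry 0, the empty model, is 0). Subsets are
// solved with a rank-revealing Cholesky: a pivot below tolerance marks an
// exactly collinear predictor, which is skipped -- R2 is then that of a
// maximal independent sub-subset, i.e. redundant predictors add nothing.
// [[Rcpp::export]]
NumericVector all_subset_r2_cpp(NumericMatrix Rxx, NumericVector rxy) {
  const int p = rxy.size();
  if (p < 1 || p > 25) stop("number of predictors must be in 1..25");
  if (Rxx.nrow() != p || Rxx.ncol() != p) stop("Rxx must be p x p");
  const size_t total = ((size_t)1) << p;
  NumericVector out(total);

  std::vector<int> idx(p);
  std::vector<double> A((size_t)p * p), b(p), L((size_t)p * p), y(p);
  const double tol = 1e-10;

  for (size_t mask = 1; mask < total; ++mask) {
    int k = 0;
    for (int i = 0; i < p; ++i)
      if ((mask >> i) & 1) idx[k++] = i;
    for (int j = 0; j < k; ++j) {
      b[j] = rxy[idx[j]];
      for (int i = 0; i < k; ++i) A[(size_t)j * k + i] = Rxx(idx[i], idx[j]);
    }
    // rank-revealing Cholesky, column skip on tiny pivot
    for (int j = 0; j < k; ++j) {
      double d = A[(size_t)j * k + j];
      for (int c = 0; c < j; ++c) d -= L[(size_t)c * k + j] * L[(size_t)c * k + j];
      if (d <= tol) {
        for (int i = j; i < k; ++i) L[(size_t)j * k + i] = 0.0;
        continue;
      }
      const double dj = std::sqrt(d);
      L[(size_t)j * k + j] = dj;
      for (int i = j + 1; i < k; ++i) {
        double s = A[(size_t)j * k + i];
        for (int c = 0; c < j; ++c) s -= L[(size_t)c * k + i] * L[(size_t)c * k + j];
        L[(size_t)j * k + i] = s / dj;
      }
    }
    double r2 = 0.0;
    for (int j = 0; j < k; ++j) {
      const double dj = L[(size_t)j * k + j];
      if (dj == 0.0) { y[j] = 0.0; continue; }
      double s = b[j];
      for (int c = 0; c < j; ++c) s -= L[(size_t)c * k + j] * y[c];
      y[j] = s / dj;
      r2 += y[j] * y[j];
    }
    out[mask] = r2;
  }
  return out;
}
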