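#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// in-place transform of a scaled squared-distance matrix into the
// cross-covariance sigf2 * k(.); the caller owns S and must treat it as
// destroyed. Negative distances (BLAS round-off) are clamped to zero.
// kernel codes: 0 squared exponential, 1 Matern 3/2, 2 Matern 5/2
// [[Rcpp::export(name = ".corr_inplace")]]
NumericMatrix corr_inplace(NumericMatrix S, NumericVector a2,
                           NumericVector b2, double sigf2, int kernel) {
  const int m = S.nrow(), n = S.ncol();
  if (a2.size() != m || b2.size() != n) stop("dimension mismatch");
  double* p = S.begin();
  const double s3 = std::sqrt(3.0), s5 = std::sqrt(5.0);
  for (int j = 0; j < n; ++j) {
  const double bj = b2[j];
  double* pj = p + (R_xlen_t)j * m;
  for (int i = 0; i < m; ++i) {
    double s = a2[i] + bj - 2.0 * pj[i];
    if (s < 0.0) s = 0.0;
    double v;
    if (kernel == 0) {
      v = std::exp(-0.5 * s);
    } else if (kernel == 1) {
      double r = std::sqrt(s);
      v = (1.0 + s3 * r) * std::exp(-s3 * r);
    } else {
      double r = std::sqrt(s);
      v = (1.0 + s5 * r + (5.0 / 3.0) * s) * std::exp(-s5 * r);
    }
    pj[i] = sigf2 * v;
  }
  }
  return S;
}

// rowSums(A * B) without materialising the elementwise product
// [[Rcpp::export(name = ".rowdot")]]
NumericVector rowdot(NumericMatrix A, NumericMatrix B) {
  const int m = A.nrow(), n = A.ncol();
  if (B.nrow() != m || B.ncol() != n) stop("dimension mismatch");
  NumericVector out(m);
  const double* a = A.begin();
  const double* b = B.begin();
  for (int j = 0; j < n; ++j) {
    const double* aj = a + (R_xlen_t)j * m;
    const double* bj = b + (R_xlen_t)j * m;
    for (int i = 0; i < m; ++i) out[i] += aj[i] * bj[i];
  }
  return out;
}

// cross-covariance sigf2 * k(x*, x) between test and training inputs on the
// unit cube; kernel codes: 0 squared exponential, 1 Matern 3/2, 2 Matern 5/2
// [[Rcpp::export(name = ".cross_cov")]]
NumericMatrix cross_cov(NumericMatrix Xstar, NumericMatrix X,
                        NumericVector ell, double sigf2, int kernel) {
  const int m = Xstar.nrow(), n = X.nrow(), D = X.ncol();
  if (Xstar.ncol() != D) stop("dimension mismatch");
  std::vector<double> inv2(D);
  for (int k = 0; k < D; ++k) inv2[k] = 1.0 / (ell[k] * ell[k]);
  NumericMatrix out(m, n);
  const double s3 = std::sqrt(3.0), s5 = std::sqrt(5.0);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      double s = 0.0;
      for (int k = 0; k < D; ++k) {
        double d = Xstar(i, k) - X(j, k);
        s += d * d * inv2[k];
      }
      double v;
      if (kernel == 0) {
        v = std::exp(-0.5 * s);
      } else if (kernel == 1) {
        double r = std::sqrt(s);
        v = (1.0 + s3 * r) * std::exp(-s3 * r);
      } else {
        double r = std::sqrt(s);
        v = (1.0 + s5 * r + (5.0 / 3.0) * s) * std::exp(-s5 * r);
      }
      out(i, j) = sigf2 * v;
    }
  }
  return out;
}
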