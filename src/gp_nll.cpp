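// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// negative log marginal likelihood of the residual GP and its gradient in
// theta = c(log ell_1..D, log sigf2, log sign2); kernel codes as in
// gp_kernels.cpp. Returns NULL-equivalent error via Rcpp::stop when the
// covariance cannot be factorised even after the jitter ladder.
// [[Rcpp::export(name = ".gp_nll_grad")]]
List gp_nll_grad(const arma::mat& X, const arma::vec& r,
                 const arma::vec& theta, int kernel) {
  const int n = X.n_rows, D = X.n_cols;
  arma::vec ell = arma::exp(theta.subvec(0, D - 1));
  const double sigf2 = std::exp(theta[D]);
  const double sign2 = std::exp(theta[D + 1]);

  arma::mat Xs = X;
  for (int k = 0; k < D; ++k) Xs.col(k) /= ell[k];
  arma::vec sq = arma::sum(Xs % Xs, 1);
  arma::mat S = -2.0 * (Xs * Xs.t());
  S.each_col() += sq;
  S.each_row() += sq.t();
  S.transform([](double v) { return v < 0.0 ? 0.0 : v; });

  const double s3 = std::sqrt(3.0), s5 = std::sqrt(5.0);
  arma::mat R(n, n), G(n, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = S(i, j), v, g;
      if (kernel == 0) {
        v = std::exp(-0.5 * s);
        g = v;
      } else if (kernel == 1) {
        double rr = std::sqrt(s);
        double e = std::exp(-s3 * rr);
        v = (1.0 + s3 * rr) * e;
        g = 3.0 * e;
      } else {
        double rr = std::sqrt(s);
        double e = std::exp(-s5 * rr);
        v = (1.0 + s5 * rr + (5.0 / 3.0) * s) * e;
        g = (5.0 / 3.0) * (1.0 + s5 * rr) * e;
      }
      R(i, j) = v;
      G(i, j) = g;
    }
  }

  arma::mat K = sigf2 * R;
  K.diag() += sign2;
  arma::mat U;
  double jitterUsed = 0.0;
  if (!arma::chol(U, K)) {
    const double scale = arma::mean(K.diag());
    bool ok = false;
    for (double j = 1e-10; j <= 1e-6 * 1.0000001; j *= 100) {
      arma::mat Kj = K;
      Kj.diag() += j * scale;
      if (arma::chol(U, Kj)) { ok = true; jitterUsed = j * scale; break; }
    }
    if (!ok) stop("covariance not positive definite after jitter");
  }

  arma::vec alpha = arma::solve(arma::trimatu(U),
                                arma::solve(arma::trimatl(U.t()), r));
  double nll = 0.5 * arma::dot(r, alpha) +
    arma::accu(arma::log(U.diag())) + 0.5 * n * std::log(2.0 * M_PI);

  arma::mat Ui = arma::inv(arma::trimatu(U));
  arma::mat Kinv = Ui * Ui.t();
  arma::mat W = alpha * alpha.t() - Kinv;   // dLogLik/dK = W/2

  arma::vec grad(D + 2, arma::fill::zeros);
  // lengthscale gradients: one fused pass over the upper triangle
  for (int j = 1; j < n; ++j) {
    for (int i = 0; i < j; ++i) {
      double wg = W(i, j) * G(i, j);
      for (int k = 0; k < D; ++k) {
        double d = X(i, k) - X(j, k);
        grad[k] += wg * d * d;
      }
    }
  }
  for (int k = 0; k < D; ++k)
    grad[k] *= -sigf2 / (ell[k] * ell[k]);   // x2 symmetry, x(-1/2)
  grad[D] = -0.5 * sigf2 * arma::accu(W % R);
  grad[D + 1] = -0.5 * sign2 * arma::trace(W);

  return List::create(_["value"] = nll, _["grad"] = NumericVector(grad.begin(),
                      grad.end()), _["jitter"] = jitterUsed);
}
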