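# naive direct-inversion GP oracle: explicit loops and solve(), kept
# independent of the package's vectorised/Cholesky implementation

naiveCorr <- function(x1, x2, ell, kernel) {
  d2 <- sum(((x1 - x2) / ell)^2)
  r <- sqrt(d2)
  switch(kernel,
    squared_exponential = exp(-d2 / 2),
    matern32 = (1 + sqrt(3) * r) * exp(-sqrt(3) * r),
    matern52 = (1 + sqrt(5) * r + 5 * d2 / 3) * exp(-sqrt(5) * r))
}

naiveCov <- function(X1, X2, ell, sigf2, kernel) {
  K <- matrix(0, nrow(X1), nrow(X2))
  for (i in seq_len(nrow(X1)))
    for (j in seq_len(nrow(X2)))
      K[i, j] <- sigf2 * naiveCorr(X1[i, ], X2[j, ], ell, kernel)
  K
}

# log marginal likelihood of residuals under the emulator's hyperparameters
naiveLogLik <- function(em) {
  X <- em@Xunit
  r <- em@resid
  K <- naiveCov(X, X, em@lengthscales, em@sigf2, em@kernel) +
    diag(em@sign2, nrow(X))
  -0.5 * drop(t(r) %*% solve(K, r)) -
    0.5 * determinant(K, logarithm = TRUE)$modulus[1] -
    0.5 * nrow(X) * log(2 * pi)
}

# predictive mean/variance at physical-unit points by direct inversion
naivePredict <- function(em, Xstar) {
  lo <- em@space@lower
  hi <- em@space@upper
  U <- sweep(sweep(as.matrix(Xstar), 2, lo, "-"), 2, hi - lo, "/")
  Xu <- em@Xunit
  K <- naiveCov(Xu, Xu, em@lengthscales, em@sigf2, em@kernel) +
    diag(em@sign2, nrow(Xu))
  Kinv <- solve(K)
  H <- buildBasis(U, em@degree)
  m <- v <- numeric(nrow(U))
  for (i in seq_len(nrow(U))) {
    k <- drop(naiveCov(U[i, , drop = FALSE], Xu, em@lengthscales, em@sigf2,
                       em@kernel))
    m[i] <- sum(H[i, ] * em@beta) + drop(t(k) %*% Kinv %*% em@resid)
    v[i] <- em@sigf2 + em@sign2 - drop(t(k) %*% Kinv %*% k)
  }
  list(mean = em@yCenter + em@yScale * m, var = em@yScale^2 * pmax(v, 0))
}
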