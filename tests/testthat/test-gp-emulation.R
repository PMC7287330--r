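sp2 <- parameterSpace(c("a", "b"), c(0, 0), c(1, 1))

smoothData <- function(n, seed = 1, noise = 0) {
  withr <- NULL # explicit local RNG scope
  set.seed(seed)
  X <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- sin(3 * X[, 1]) * exp(X[, 2]) + 0.5 * X[, 2]^2 +
    noise * rnorm(n)
  list(X = X, y = y)
}

test_that("polynomial basis has the combinatorial column count", {
  X2 <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("x1", "x2")))
  H <- buildBasis(X2, 2)
  expect_equal(ncol(H), choose(2 + 2, 2))  # 6
  expect_true(all(c("(Intercept)") %in% colnames(H)))
  # columns include the cross term x1*x2
  expect_true(any(grepl("x1\\^1\\*x2\\^1", colnames(H))))
  X8 <- matrix(runif(80), 10, 8)
  expect_equal(ncol(buildBasis(X8, 1)), 9)
  expect_equal(ncol(buildBasis(X8, 3)), choose(11, 3))  # 165
  expect_error(buildBasis(X8, 4), class = "ew_gp_error")
})

test_that("least-squares mean recovers members of its model class", {
  set.seed(4)
  X <- matrix(runif(60), 20, 3)
  yLin <- 2 + 3 * X[, 1]
  fit <- fitMeanFunction(X, yLin, 1)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  yConst <- rep(5, 20)
  fitC <- fitMeanFunction(X, yConst, 2)
  expect_equal(unname(fitC$beta[1]), 5)
  expect_lt(max(abs(fitC$beta[-1])), 1e-10)
  # normal equations: residuals orthogonal to the basis
  set.seed(5)
  Xr <- matrix(runif(150), 50, 3)
  yr <- rnorm(50)
  fr <- fitMeanFunction(Xr, yr, 2)
  expect_lt(max(abs(crossprod(fr$H, fr$residuals))), 1e-8)
})

test_that("prediction and likelihood match a naive direct-inversion oracle", {
  dat <- smoothData(40, seed = 11, noise = 0.05)
  set.seed(12)
  Xstar <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  for (kern in c("squared_exponential", "matern32", "matern52")) {
    for (deg in 1:3) {
      em <- gpEmulator(dat$X, dat$y, sp2, degree = deg, kernel = kern,
                       restarts = 3, seed = 7)
      expect_lt(abs(em@logLik - naiveLogLik(em)), 1e-8)
      pr <- predict(em, Xstar)
      nv <- naivePredict(em, Xstar)
      expect_lt(max(abs(pr$mean - nv$mean)), 1e-8)
      expect_lt(max(abs(pr$var - nv$var)), 1e-8)
    }
  }
})

test_that("GP interpolates noise-free data and reverts to the prior far away", {
  dat <- smoothData(30, seed = 2)
  em <- gpEmulator(dat$X, dat$y, sp2, degree = 1, kernel = "matern52",
                   restarts = 5, seed = 3)
  prT <- predict(em, dat$X[1:5, , drop = FALSE])
  expect_equal(prT$mean, dat$y[1:5], tolerance = 1e-3)
  expect_lt(max(prT$var), 1e-4 * var(dat$y))
  # far outside the data (allowed: near/inside the box) variance approaches
  # the prior level sigf2 + sign2
  far <- matrix(c(40, 40), 1, dimnames = list(NULL, c("a", "b")))
  prF <- predict(em, far)
  expect_equal(prF$var, em@yScale^2 * (em@sigf2 + em@sign2),
               tolerance = 1e-6)
})

test_that("pure-noise residuals are absorbed by the nugget", {
  set.seed(9)
  X <- matrix(runif(400), 200, 2)
  r <- rnorm(200)
  gp <- fitResidualGP(X, r, kernel = "squared_exponential", restarts = 5,
                      seed = 1)
  expect_gt(gp$sign2 / var(r), 0.8)
})

test_that("lengthscales are recoverable from a known GP draw", {
  set.seed(31)
  n <- 200
  X <- matrix(sort(runif(n)), n, 1)
  ellTrue <- 0.2
  K <- exp(-0.5 * outer(X[, 1], X[, 1], "-")^2 / ellTrue^2)
  r <- drop(chol(K + 1e-10 * diag(n)) %*% rnorm(n))
  r <- r - mean(r)
  gp <- fitResidualGP(X, r, kernel = "squared_exponential", restarts = 6,
                      seed = 2)
  expect_gt(gp$lengthscales[1], ellTrue / 2)
  expect_lt(gp$lengthscales[1], ellTrue * 2)
})

test_that("duplicate training points survive via the jitter ladder", {
  set.seed(6)
  X <- matrix(runif(40), 20, 2)
  X[2, ] <- X[1, ]
  y <- sin(3 * X[, 1]) + X[, 2]^2   # equal values at the duplicated input
  em <- gpEmulator(X, y, sp2, degree = 1, restarts = 2, seed = 1)
  expect_true(is.finite(em@logLik))
  pr <- predict(em, X[1:2, , drop = FALSE])
  expect_true(all(is.finite(pr$mean)))
})

test_that("cross-validation separates signal from noise and keeps books", {
  dat <- smoothData(150, seed = 21, noise = 0.01)
  cv <- crossValidate(dat$X, dat$y, sp2,
                      candidates = list(list(degree = 2, kernel = "matern52")),
                      folds = 5, seed = 2, restarts = 3)
  expect_gt(cv$bestR2, 0.95)
  # training R2 of the selected spec is at least the CV score (overfit check)
  em <- gpEmulator(dat$X, dat$y, sp2, degree = 2, kernel = "matern52",
                   restarts = 3, seed = 3)
  prT <- predict(em, dat$X)
  r2Train <- 1 - sum((dat$y - prT$mean)^2) / sum((dat$y - mean(dat$y))^2)
  expect_gte(r2Train, cv$bestR2 - 0.01)

  set.seed(22)
  yNoise <- rnorm(150)
  cvN <- crossValidate(dat$X, yNoise, sp2,
                       candidates = list(list(degree = 1,
                                              kernel = "matern52")),
                       folds = 5, seed = 2, restarts = 3)
  expect_lt(cvN$bestR2, 0.1)

  cv9 <- crossValidate(dat$X[1:60, ], dat$y[1:60], sp2, folds = 5, seed = 4,
                       restarts = 2)
  expect_equal(nrow(cv9$scores), 9L)
  expect_error(crossValidate(dat$X[1:3, ], dat$y[1:3], sp2, folds = 5),
               class = "ew_gp_error")
})

test_that("a constant feature degenerates to a mean-only emulator", {
  sp <- toySpace()
  X <- designPoints(latinHypercube(sp, 30, seed = 1))
  Y <- cbind(EDV = 100 + 20 * X[, 1], ESV = rep(42, 30))
  expect_warning(
    bank <- trainEmulatorBank(X, Y = Y, space = sp,
                              specs = list(list(degree = 1,
                                                kernel = "matern52")),
                              cvFolds = 0, restarts = 2, seed = 1),
    "constant")
  pr <- predict(bank[["ESV"]], X[1:4, , drop = FALSE])
  expect_equal(pr$mean, rep(42, 4), tolerance = 1e-8)
})
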