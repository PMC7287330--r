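# ---- polynomial mean function -------------------------------------------

# all multi-indices of total degree exactly t in D variables
composeDegree <- function(D, t) {
  if (D == 1) return(matrix(t, 1, 1))
  do.call(rbind, lapply(0:t, function(k) cbind(k, composeDegree(D - 1, t - k))))
}

monomialExponents <- function(D, degree) {
  do.call(rbind, lapply(0:degree, function(t) composeDegree(D, t)))
}

#' Polynomial regression basis
#'
#' Builds the design matrix of all monomials of total degree up to
#' \code{degree}, including the intercept and all cross terms; the column
#' count is \code{choose(D + degree, degree)}.
#'
#' @param X n x D matrix of inputs (expected on the unit cube).
#' @param degree polynomial degree: 1, 2 or 3.
#' @return n x q basis matrix with monomial column names.
#' @examples
#' dim(buildBasis(matrix(runif(10 * 8), 10), degree = 3))  # q = 165
#' @export
buildBasis <- function(X, degree) {
  if (!degree %in% 1:3)
    ewStop("ew_gp_error", "mean degree must be 1, 2 or 3")
  X <- as.matrix(X)
  D <- ncol(X)
  E <- monomialExponents(D, degree)
  vn <- colnames(X)
  if (is.null(vn)) vn <- paste0("x", seq_len(D))
  H <- matrix(1, nrow(X), nrow(E))
  nm <- character(nrow(E))
  for (j in seq_len(nrow(E))) {
    e <- E[j, ]
    act <- which(e > 0)
    for (k in act) H[, j] <- H[, j] * X[, k]^e[k]
    nm[j] <- if (length(act) == 0) "(Intercept)" else
      paste(sprintf("%s^%d", vn[act], e[act]), collapse = "*")
  }
  colnames(H) <- nm
  H
}

#' Fit the polynomial mean function by least squares
#'
#' Ordinary least squares on the monomial basis; on rank deficiency a small
#' ridge penalty is substituted with a warning.
#'
#' @param X n x D inputs on the unit cube.
#' @param y response vector.
#' @param degree polynomial degree (1, 2 or 3).
#' @return list with \code{beta} (coefficients), \code{residuals} and the
#'   basis \code{H}.
#' @export
fitMeanFunction <- function(X, y, degree) {
  H <- buildBasis(X, degree)
  qrH <- qr(H)
  if (qrH$rank < ncol(H)) {
    warning("rank-deficient mean basis; using ridge fallback")
    lam <- 1e-8 * mean(diag(crossprod(H)))
    beta <- solve(crossprod(H) + lam * diag(ncol(H)), crossprod(H, y))
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrH, y)
  }
  names(beta) <- colnames(H)
  fit <- drop(H %*% beta)
  list(beta = beta, residuals = y - fit, H = H)
}

# ---- kernels --------------------------------------------------------------

kernelNames <- function() c("squared_exponential", "matern32", "matern52")

# correlation from the scaled squared distance S = sum_k d_k^2 / ell_k^2,
# plus the factor G such that dK/dlog(ell_k) = sigf2 * G * D2_k / ell_k^2
corrFromS <- function(kernel, S, withGrad = FALSE) {
  if (kernel == "squared_exponential") {
    R <- exp(-0.5 * S)
    G <- if (withGrad) R
  } else if (kernel == "matern32") {
    r <- sqrt(pmax(S, 0))
    e <- exp(-sqrt(3) * r)
    R <- (1 + sqrt(3) * r) * e
    G <- if (withGrad) 3 * e
  } else if (kernel == "matern52") {
    r <- sqrt(pmax(S, 0))
    e <- exp(-sqrt(5) * r)
    R <- (1 + sqrt(5) * r + (5 / 3) * S) * e
    G <- if (withGrad) (5 / 3) * (1 + sqrt(5) * r) * e
  } else ewStop("ew_gp_error", paste("unknown kernel:", kernel))
  if (withGrad) list(R = R, G = G) else R
}

pairwiseSqDiff <- function(X) {
  lapply(seq_len(ncol(X)), function(k) outer(X[, k], X[, k], "-")^2)
}

# scaled squared cross-distances via BLAS: |a|^2 + |b|^2 - 2 a.b
crossSqDist <- function(Xstar, X, ell) {
  A <- sweep(Xstar, 2, ell, "/")
  B <- sweep(X, 2, ell, "/")
  S <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(S, 0)
}

# Cholesky with an escalating jitter ladder
cholJitter <- function(K, ladder = 10^seq(-10, -6)) {
  n <- nrow(K)
  U <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(U)) return(list(U = U, jitter = 0))
  scale <- mean(diag(K))
  for (j in ladder) {
    U <- tryCatch(chol(K + j * scale * diag(n)), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, jitter = j * scale))
  }
  ewStop("ew_gp_error", "covariance not positive definite after jitter")
}

# negative log marginal likelihood and its gradient in
# theta = c(log ell_1..D, log sigf2, log sign2)
gpNegLogLik <- function(theta, D2, r, kernel) {
  D <- length(D2)
  ell <- exp(theta[seq_len(D)])
  sigf2 <- exp(theta[D + 1])
  sign2 <- exp(theta[D + 2])
  n <- length(r)
  S <- matrix(0, n, n)
  for (k in seq_len(D)) S <- S + D2[[k]] / ell[k]^2
  cg <- corrFromS(kernel, S, withGrad = TRUE)
  K <- sigf2 * cg$R
  diag(K) <- diag(K) + sign2
  ch <- cholJitter(K)
  U <- ch$U
  alpha <- backsolve(U, forwardsolve(t(U), r))
  nll <- 0.5 * sum(r * alpha) + sum(log(diag(U))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(U)
  W <- tcrossprod(alpha) - Kinv   # dLL/dK = W/2
  g <- numeric(D + 2)
  for (k in seq_len(D))
    g[k] <- -0.5 * sigf2 * sum(W * cg$G * D2[[k]]) / ell[k]^2
  g[D + 1] <- -0.5 * sigf2 * sum(W * cg$R)
  g[D + 2] <- -0.5 * sign2 * sum(diag(W))
  list(value = nll, grad = g)
}

#' Fit GP hyperparameters to mean-function residuals
#'
#' Maximises the log marginal likelihood of a zero-mean anisotropic GP over
#' log-parameterised lengthscales, signal variance and nugget, using
#' L-BFGS-B with analytic gradients and multiple seeded restarts
#' (initialisations log-uniform in ell in [0.05, 5], signal variance in
#' [0.1, 10] x var(r), nugget in [1e-6, 0.1] x var(r)).
#'
#' @param X n x D inputs on the unit cube.
#' @param r residual vector (data minus fitted mean).
#' @param kernel one of \code{"squared_exponential"}, \code{"matern32"},
#'   \code{"matern52"}.
#' @param restarts number of random restarts.
#' @param seed integer seed for the restarts.
#' @param init optional warm-start list with \code{lengthscales},
#'   \code{sigf2}, \code{sign2}, used as the first restart.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param factr L-BFGS-B convergence factor (looser values stop earlier).
#' @return list with \code{lengthscales}, \code{sigf2}, \code{sign2} and the
#'   attained \code{logLik}.
#' @export
fitResidualGP <- function(X, r, kernel = "matern52", restarts = 10,
                          seed = 1L, init = NULL, maxit = 100,
                          factr = 1e9) {
  X <- as.matrix(X)
  D <- ncol(X)
  n <- length(r)
  vr <- var(r) * (n - 1) / n
  if (!is.finite(vr) || vr < 1e-12) {
    # degenerate (constant) residuals: mean-only emulator
    return(list(lengthscales = rep(1, D), sigf2 = 1e-12, sign2 = 1e-12,
                logLik = NA_real_, degenerate = TRUE))
  }
  kcode <- match(kernel, kernelNames()) - 1L
  if (is.na(kcode)) ewStop("ew_gp_error", paste("unknown kernel:", kernel))
  lowerB <- c(rep(log(1e-2), D), log(1e-8 * vr), log(1e-9 * vr))
  upperB <- c(rep(log(50), D), log(1e3 * vr), log(10 * vr))
  # cache the joint value/gradient evaluation for optim's fn/gr pair
  cache <- new.env(parent = emptyenv())
  evalAt <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- .gp_nll_grad(X, r, theta, kcode)
      cache$key <- key
    }
    cache$val
  }
  inits <- list()
  if (!is.null(init))
    inits[[1]] <- c(log(init$lengthscales), log(init$sigf2),
                    log(max(init$sign2, 1e-9 * vr)))
  nRand <- max(0, restarts - length(inits))
  if (nRand > 0) {
    rnd <- withSeed(seed, {
      lapply(seq_len(nRand), function(i) {
        c(runif(D, log(0.05), log(5)),
          log(vr) + runif(1, log(0.1), log(10)),
          log(vr) + runif(1, log(1e-6), log(0.1)))
      })
    })
    inits <- c(inits, rnd)
  }
  best <- NULL
  for (th0 in inits) {
    th0 <- pmin(pmax(th0, lowerB), upperB)
    fit <- tryCatch(
      optim(th0, fn = function(th) evalAt(th)$value,
            gr = function(th) evalAt(th)$grad,
            method = "L-BFGS-B", lower = lowerB, upper = upperB,
            control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    ewStop("ew_gp_error", "GP hyperparameter optimisation failed")
  th <- best$par
  list(lengthscales = exp(th[seq_len(D)]), sigf2 = exp(th[D + 1]),
       sign2 = exp(th[D + 2]), logLik = -best$value, degenerate = FALSE)
}

# ---- the emulator ---------------------------------------------------------

#' Train one Gaussian process emulator
#'
#' Two-step universal-kriging fit on standardised data: the polynomial mean
#' is fitted by least squares, then the GP hyperparameters are fitted to the
#' residuals by maximum marginal likelihood. The mean coefficients are
#' treated as fixed in prediction (their uncertainty is not propagated).
#'
#' @param X n x D training inputs in physical units.
#' @param y response vector (one output feature).
#' @param space the input \linkS4class{ParameterSpace}.
#' @param degree polynomial mean degree (1, 2 or 3).
#' @param kernel GP kernel name.
#' @param restarts,seed,init,maxit,factr passed to
#'   \code{\link{fitResidualGP}}.
#' @param featureName label stored with the emulator.
#' @param cvR2 optional cross-validation score to record.
#' @return a \linkS4class{GPEmulator}.
#' @examples
#' sp <- parameterSpace("x", 0, 1)
#' X <- matrix(seq(0, 1, length.out = 20), dimnames = list(NULL, "x"))
#' em <- gpEmulator(X, sin(2 * pi * X[, 1]), sp, degree = 1, restarts = 3)
#' predict(em, matrix(0.25, dimnames = list(NULL, "x")))
#' @export
gpEmulator <- function(X, y, space, degree = 2, kernel = "matern52",
                       restarts = 10, seed = 1L, init = NULL, maxit = 100,
                       factr = 1e9, featureName = "y", cvR2 = NA_real_) {
  U <- toUnit(space, X)
  n <- nrow(U)
  if (n < 2) ewStop("ew_gp_error", "at least two training points required")
  yc <- mean(y)
  ys <- sd(y)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  z <- (y - yc) / ys
  mf <- fitMeanFunction(U, z, degree)
  gp <- fitResidualGP(U, mf$residuals, kernel = kernel, restarts = restarts,
                      seed = seed, init = init, maxit = maxit, factr = factr)
  S <- crossSqDist(U, U, gp$lengthscales)
  K <- gp$sigf2 * corrFromS(kernel, S)
  diag(K) <- diag(K) + gp$sign2
  ch <- cholJitter(K)
  Kinv <- chol2inv(ch$U)
  alpha <- drop(Kinv %*% mf$residuals)
  new("GPEmulator", featureName = featureName, kernel = kernel,
      degree = degree, beta = mf$beta, lengthscales = gp$lengthscales,
      sigf2 = gp$sigf2, sign2 = gp$sign2,
      logLik = if (is.na(gp$logLik)) NA_real_ else gp$logLik,
      space = space, Xunit = U, resid = mf$residuals, alpha = alpha,
      L = ch$U, Kinv = Kinv, yCenter = yc, yScale = ys, cvR2 = cvR2)
}

#' Predict from a GP emulator
#'
#' Predictive mean \code{h(x) beta + k* K^-1 r} and variance
#' \code{sigf2 + sign2 - k* K^-1 k*} (clipped at zero), back-transformed to
#' the output's original units.
#'
#' @param object a \linkS4class{GPEmulator}.
#' @param newdata points in physical units (matrix or single point).
#' @param ... unused.
#' @return list with numeric vectors \code{mean} and \code{var}.
#' @export
setMethod("predict", "GPEmulator", function(object, newdata, ...) {
  Ustar <- toUnit(object@space, newdata)
  nstar <- nrow(Ustar)
  m <- v <- numeric(nstar)
  # chunk rows to bound the nstar x n cross-covariance memory
  chunk <- 32768L
  for (s in seq(1L, nstar, by = chunk)) {
    ix <- s:min(s + chunk - 1L, nstar)
    Uc <- Ustar[ix, , drop = FALSE]
    mu <- drop(buildBasis(Uc, object@degree) %*% object@beta)
    A <- sweep(Uc, 2, object@lengthscales, "/")
    B <- sweep(object@Xunit, 2, object@lengthscales, "/")
    kstar <- .corr_inplace(tcrossprod(A, B), rowSums(A^2), rowSums(B^2),
                           object@sigf2,
                           match(object@kernel, kernelNames()) - 1L)
    m[ix] <- mu + drop(kstar %*% object@alpha)
    vv <- object@sigf2 + object@sign2 -
      .rowdot(kstar %*% object@Kinv, kstar)
    vv[vv < 0] <- 0
    v[ix] <- vv
  }
  list(mean = object@yCenter + object@yScale * m,
       var = object@yScale^2 * v)
})

setMethod("show", "GPEmulator", function(object) {
  cat(sprintf(
    "GPEmulator '%s': degree-%d mean + %s GP, n = %d, logLik %.2f, cvR2 %s\n",
    object@featureName, object@degree, object@kernel, nrow(object@Xunit),
    object@logLik, ifelse(is.na(object@cvR2), "NA",
                          sprintf("%.3f", object@cvR2))))
})

# ---- model selection ------------------------------------------------------

#' Default emulator candidate grid
#'
#' All combinations of mean degree 1..3 with the three anisotropic kernels.
#'
#' @return list of \code{list(degree, kernel)} candidates (length 9).
#' @export
defaultEmulatorSpecs <- function() {
  out <- list()
  for (d in 1:3)
    for (k in kernelNames())
      out[[length(out) + 1]] <- list(degree = d, kernel = k)
  out
}

#' Select an emulator spec by k-fold cross-validation
#'
#' Splits the data into k seeded shuffled folds; for each candidate
#' (degree, kernel) pair, trains on k-1 folds and scores R-squared on the
#' held-out fold; the spec with the highest mean R-squared wins. Ties are
#' broken towards the lower degree, then Matern 5/2 over Matern 3/2 over
#' squared exponential.
#'
#' @param X n x D inputs in physical units.
#' @param y response vector.
#' @param space the input \linkS4class{ParameterSpace}.
#' @param candidates list of \code{list(degree, kernel)} specs.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param restarts,maxit passed to the GP fit.
#' @return list with \code{best} (the winning spec), \code{bestR2} and
#'   \code{scores} (data.frame of per-candidate mean R-squared).
#' @export
crossValidate <- function(X, y, space, candidates = defaultEmulatorSpecs(),
                          folds = 5, seed = 1L, restarts = 5, maxit = 60) {
  X <- asPointMatrix(space, X)
  n <- nrow(X)
  if (n < folds) ewStop("ew_gp_error", "fewer points than folds")
  fold <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  scoreSpec <- function(spec) {
    r2 <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      em <- gpEmulator(X[tr, , drop = FALSE], y[tr], space,
                       degree = spec$degree, kernel = spec$kernel,
                       restarts = restarts, seed = childSeed(seed, f),
                       maxit = maxit)
      pr <- predict(em, X[!tr, , drop = FALSE])
      yt <- y[!tr]
      r2[f] <- 1 - sum((yt - pr$mean)^2) / sum((yt - mean(yt))^2)
    }
    mean(r2)
  }
  meanR2 <- vapply(candidates, scoreSpec, 0)
  kernRank <- c(matern52 = 1, matern32 = 2, squared_exponential = 3)
  ord <- order(-meanR2,
               vapply(candidates, function(s) s$degree, 0),
               kernRank[vapply(candidates, function(s) s$kernel, "")])
  scores <- data.frame(
    degree = vapply(candidates, function(s) s$degree, 0),
    kernel = vapply(candidates, function(s) s$kernel, ""),
    meanR2 = meanR2)
  list(best = candidates[[ord[1]]], bestR2 = meanR2[ord[1]], scores = scores)
}

#' Train one emulator per output feature
#'
#' Independent per-feature emulators over a shared input space. With several
#' candidate specs, each feature's spec is selected by cross-validation;
#' with exactly one spec, it is used directly (optionally still scoring it
#' by CV when \code{cvFolds > 0}). A constant feature column degenerates to
#' a mean-only emulator with a warning.
#'
#' @param x a \code{SummarizedExperiment} from \code{\link{simulateBatch}}
#'   (failed simulations are excluded automatically), or an n x D input
#'   matrix when \code{Y} is given.
#' @param Y n x F feature matrix (when \code{x} is a matrix).
#' @param space input \linkS4class{ParameterSpace} (taken from the batch
#'   metadata when \code{x} is a SummarizedExperiment).
#' @param features feature columns to emulate (default: all).
#' @param specs candidate list; default the 9-spec grid.
#' @param cvFolds folds for selection/scoring; 0 skips CV when a single
#'   spec is given.
#' @param restarts,seed,maxit,factr GP fit controls.
#' @param inits optional named list of warm starts per feature.
#' @return an \linkS4class{EmulatorBank}.
#' @export
trainEmulatorBank <- function(x, Y = NULL, space = NULL, features = NULL,
                              specs = defaultEmulatorSpecs(), cvFolds = 5,
                              restarts = 10, seed = 1L, maxit = 100,
                              factr = 1e9, inits = NULL) {
  if (is(x, "SummarizedExperiment")) {
    if (is.null(space)) space <- S4Vectors::metadata(x)$space
    tv <- trainingView(x)
    X <- tv$X; Y <- tv$Y
  } else {
    X <- asPointMatrix(space, x)
  }
  if (is.null(colnames(Y)))
    ewStop("ew_gp_error", "feature matrix must have column names")
  if (is.null(features)) features <- colnames(Y)
  stopifnot(all(features %in% colnames(Y)))
  ems <- list()
  for (j in seq_along(features)) {
    fn <- features[j]
    y <- Y[, fn]
    sj <- childSeed(seed, j)
    if (sd(y) < 1e-12) {
      warning(sprintf("feature '%s' is constant; mean-only emulator", fn))
      ems[[fn]] <- gpEmulator(X, y, space, degree = 1,
                              kernel = "squared_exponential", restarts = 1,
                              seed = sj, featureName = fn)
      next
    }
    if (length(specs) > 1) {
      sel <- crossValidate(X, y, space, candidates = specs,
                           folds = cvFolds, seed = sj,
                           restarts = max(2, restarts %/% 2))
      spec <- sel$best; cv <- sel$bestR2
    } else {
      spec <- specs[[1]]
      cv <- NA_real_
      if (cvFolds > 0) {
        sel <- crossValidate(X, y, space, candidates = specs,
                             folds = cvFolds, seed = sj,
                             restarts = max(2, restarts %/% 2))
        cv <- sel$bestR2
      }
    }
    ems[[fn]] <- gpEmulator(X, y, space, degree = spec$degree,
                            kernel = spec$kernel, restarts = restarts,
                            seed = sj, featureName = fn, cvR2 = cv,
                            init = inits[[fn]], maxit = maxit, factr = factr)
  }
  new("EmulatorBank", emulators = ems)
}

#' @describeIn trainEmulatorBank features covered by a bank.
#' @param bank an \linkS4class{EmulatorBank}.
#' @export
bankFeatures <- function(bank) names(bank@emulators)

setMethod("length", "EmulatorBank", function(x) length(x@emulators))

#' Extract one emulator from a bank
#' @param x an \linkS4class{EmulatorBank}.
#' @param i feature name or index.
#' @export
setMethod("[[", "EmulatorBank", function(x, i) x@emulators[[i]])

setMethod("show", "EmulatorBank", function(object) {
  cat(sprintf("EmulatorBank with %d emulators: %s\n",
              length(object@emulators),
              paste(names(object@emulators), collapse = ", ")))
})

#' Predict all features of a bank at a set of points
#'
#' @param bank an \linkS4class{EmulatorBank}.
#' @param newdata points in physical units.
#' @return list of matrices \code{mean} and \code{var} (points x features).
#' @export
predictBank <- function(bank, newdata) {
  feats <- bankFeatures(bank)
  newdata <- asPointMatrix(bank@emulators[[1]]@space, newdata)
  m <- v <- matrix(NA_real_, nrow(newdata), length(feats),
                   dimnames = list(NULL, feats))
  for (fn in feats) {
    pr <- predict(bank@emulators[[fn]], newdata)
    m[, fn] <- pr$mean
    v[, fn] <- pr$var
  }
  list(mean = m, var = v)
}
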