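#' Saltelli estimation of Sobol sensitivity indices
#'
#' Evaluates a deterministic function over a \code{\link{saltelliDesign}}
#' and estimates first-order indices (Saltelli 2010 estimator
#' \code{mean(fB * (fAB_i - fA)) / V}), total effects (Jansen estimator
#' \code{mean((fA - fAB_i)^2) / (2 V)}) and, when \code{secondOrder},
#' closed second-order indices
#' \code{mean(fBA_i * fAB_j - fA * fB) / V - S1_i - S1_j}. Estimates are
#' reported raw (small negative values are sampling noise); clipping happens
#' only in \code{\link{aggregateContributions}}.
#'
#' @param f function taking an n x D matrix of points in physical units and
#'   returning n values (e.g. an emulator's predictive mean).
#' @param space the input \linkS4class{ParameterSpace}.
#' @param nBase Saltelli base sample size (power of two).
#' @param secondOrder estimate second-order indices.
#' @param seed integer seed for the design's digital shift.
#' @param feature label stored with the result.
#' @param design optional pre-built Saltelli design to reuse across outputs.
#' @return a \linkS4class{SobolResult}.
#' @examples
#' sp <- parameterSpace(c("x1", "x2", "x3"), rep(-pi, 3), rep(pi, 3))
#' res <- sobolIndices(ishigami, sp, nBase = 1024)
#' res@S1
#' @export
sobolIndices <- function(f, space, nBase = 2^14, secondOrder = TRUE,
                         seed = 1L, feature = "y", design = NULL) {
  if (is.null(design))
    design <- saltelliDesign(space, nBase, secondOrder = secondOrder,
                             seed = seed)
  D <- numParams(space)
  X <- designPoints(design)
  y <- as.numeric(f(X))
  if (length(y) != nrow(X))
    ewStop("ew_gsa_error", "f must return one value per design row")
  sobolFromEvaluations(y, D, secondOrder, nBase = designSize(design) %/%
                         (2L + D + if (secondOrder) D else 0L),
                       seed = design@seed, feature = feature,
                       names = paramNames(space))
}

# estimators from the stacked block evaluations
sobolFromEvaluations <- function(y, D, secondOrder, nBase, seed, feature,
                                 names) {
  bl <- saltelliBlocks(length(y), D, secondOrder)
  fA <- y[bl$A]
  fB <- y[bl$B]
  V <- var(c(fA, fB))
  if (!is.finite(V) || V < .Machine$double.eps * mean(c(fA, fB)^2 + 1))
    ewStop("ew_gsa_error", "zero total variance: Sobol indices undefined")
  S1 <- ST <- setNames(numeric(D), names)
  fAB <- lapply(bl$AB, function(ix) y[ix])
  for (i in seq_len(D)) {
    S1[i] <- mean(fB * (fAB[[i]] - fA)) / V
    ST[i] <- mean((fA - fAB[[i]])^2) / (2 * V)
  }
  S2 <- matrix(NA_real_, D, D, dimnames = list(names, names))
  if (secondOrder) {
    fBA <- lapply(bl$BA, function(ix) y[ix])
    for (i in seq_len(D - 1)) {
      for (j in (i + 1):D) {
        Vij <- mean(fBA[[i]] * fAB[[j]] - fA * fB) / V
        S2[i, j] <- Vij - S1[i] - S1[j]
      }
    }
  }
  s2sum <- if (secondOrder) sum(S2[upper.tri(S2)]) else 0
  # each pairwise index contributes to two total effects, so the
  # order->=3 remainder is sum(ST) - sum(S1) - 2 sum(S2); it vanishes for
  # functions with no interactions beyond pairs
  new("SobolResult", feature = feature, S1 = S1, S2 = S2, ST = ST,
      higherOrder = sum(ST) - sum(S1) - 2 * s2sum, totalVariance = V,
      nBase = nBase, seed = as.integer(seed))
}

setMethod("show", "SobolResult", function(object) {
  cat(sprintf("SobolResult '%s' (nBase = %d, V = %.4g)\n", object@feature,
              object@nBase, object@totalVariance))
  print(round(data.frame(S1 = object@S1, ST = object@ST,
                         row.names = names(object@S1)), 4))
  cat(sprintf("higher-order remainder: %.4f\n", object@higherOrder))
})

#' Sobol indices for every emulator in a bank
#'
#' Shares a single Saltelli design across all features for efficiency and
#' runs the estimators on each emulator's predictive mean (the emulator's
#' own uncertainty is ignored). Zero-variance features are reported as NULL
#' entries without aborting the rest of the bank.
#'
#' @param bank an \linkS4class{EmulatorBank} trained on the full space.
#' @param space the input \linkS4class{ParameterSpace}.
#' @param nBase Saltelli base sample size (power of two).
#' @param secondOrder estimate second-order indices.
#' @param seed integer seed.
#' @return named list of \linkS4class{SobolResult} (NULL for degenerate
#'   features).
#' @export
sobolBank <- function(bank, space, nBase = 2^14, secondOrder = TRUE,
                      seed = 1L) {
  design <- saltelliDesign(space, nBase, secondOrder = secondOrder,
                           seed = seed)
  out <- list()
  for (fn in bankFeatures(bank)) {
    em <- bank[[fn]]
    out[[fn]] <- tryCatch(
      sobolIndices(function(X) predict(em, X)$mean, space, nBase,
                   secondOrder = secondOrder, seed = seed, feature = fn,
                   design = design),
      ew_gsa_error = function(e) {
        warning(sprintf("feature '%s': %s", fn, conditionMessage(e)))
        NULL
      })
  }
  out
}

#' Stacked per-parameter variance contributions
#'
#' Display aggregation for stacked decompositions: each parameter is
#' attributed its first-order effect plus half of each of its second-order
#' interactions, the pairwise interactions are listed separately, and the
#' higher-order remainder counts interactions of order three and above
#' (\code{sum(ST) - sum(S1) - 2 sum(S2)}, since every pairwise index enters
#' two total effects). Negative
#' estimates (sampling noise) are clipped to zero for display; raw values
#' are kept alongside.
#'
#' @param res a \linkS4class{SobolResult} with S1, S2 and ST present.
#' @return list with \code{stack} (per-parameter display shares),
#'   \code{pairs} (pairwise interactions) and \code{higherOrder} (display
#'   and raw remainder).
#' @export
aggregateContributions <- function(res) {
  if (!is(res, "SobolResult")) ewStop("ew_gsa_error", "expects a SobolResult")
  D <- length(res@S1)
  if (all(is.na(res@S2)))
    ewStop("ew_gsa_error", "second-order indices required for aggregation")
  S2 <- res@S2
  S2full <- matrix(0, D, D)
  S2full[upper.tri(S2full)] <- S2[upper.tri(S2)]
  S2full <- S2full + t(S2full)
  shareRaw <- res@S1 + 0.5 * rowSums(S2full)
  ut <- which(upper.tri(S2), arr.ind = TRUE)
  pairs <- data.frame(
    i = names(res@S1)[ut[, 1]], j = names(res@S1)[ut[, 2]],
    S2raw = S2[upper.tri(S2)], S2 = pmax(S2[upper.tri(S2)], 0))
  list(stack = data.frame(parameter = names(res@S1), raw = shareRaw,
                          share = pmax(shareRaw, 0), row.names = NULL),
       pairs = pairs,
       higherOrder = c(display = max(res@higherOrder, 0),
                       raw = res@higherOrder))
}
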