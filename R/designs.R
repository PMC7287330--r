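#' Latin hypercube design
#'
#' Stratified uniform design: in every dimension exactly one point falls in
#' each of the n equal-width strata of the range. Generated on the unit cube
#' (via \code{lhs::randomLHS}) and rescaled to physical units.
#'
#' @param space a \linkS4class{ParameterSpace}.
#' @param n number of points (>= 1).
#' @param seed integer seed; designs are reproducible given the seed.
#' @return an \linkS4class{ExperimentalDesign} with scheme "lhd".
#' @examples
#' d <- latinHypercube(defaultParameterSpace(), 16, seed = 1)
#' designSize(d)
#' @export
latinHypercube <- function(space, n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) ewStop("ew_design_error", "n must be a positive count")
  U <- withSeed(seed, lhs::randomLHS(n, numParams(space)))
  experimentalDesign(fromUnit(space, U), space, scheme = "lhd", seed = seed)
}

#' Saltelli design for Sobol index estimation
#'
#' Builds the radial/cross-sampling block structure used by the Saltelli
#' estimators from a 2D-dimensional base-2 Sobol low-discrepancy sequence:
#' base matrices A and B, the D matrices AB_i (A with column i taken from B)
#' and, when \code{secondOrder}, the D matrices BA_i. Rows are ordered as
#' blocks A, AB_1..AB_D, (BA_1..BA_D,) B, each of \code{nBase} rows, giving
#' nBase*(2D+2) rows with second order and nBase*(D+2) without. A seeded
#' digital shift randomises the sequence while preserving its balance.
#'
#' @param space a \linkS4class{ParameterSpace}.
#' @param nBase base sample size; must be a power of two (the Sobol sequence
#'   is balanced in base-2 blocks; other sizes are rejected, never rounded).
#' @param secondOrder include the blocks needed for second-order indices.
#' @param seed integer seed for the digital shift.
#' @return an \linkS4class{ExperimentalDesign} with scheme "saltelli".
#' @examples
#' d <- saltelliDesign(defaultParameterSpace(), 8)
#' designSize(d)  # 8 * (2*8 + 2)
#' @export
saltelliDesign <- function(space, nBase, secondOrder = TRUE, seed = 1L) {
  nBase <- as.integer(nBase)
  if (is.na(nBase) || nBase < 1)
    ewStop("ew_design_error", "nBase must be a positive count")
  if (bitwAnd(nBase, nBase - 1L) != 0L)
    ewStop("ew_design_error", "nBase must be a power of two")
  D <- numParams(space)
  if (2L * D > 21L)
    ewStop("ew_design_error", "Saltelli design supports at most 10 dimensions")
  shift <- withSeed(seed, as.integer(sample.int(2147483647L, 2L * D) - 1L))
  Q <- .sobol_matrix(nBase, 2L * D, shift)
  A <- Q[, seq_len(D), drop = FALSE]
  B <- Q[, D + seq_len(D), drop = FALSE]
  blocks <- vector("list", 2L + D + if (secondOrder) D else 0L)
  blocks[[1L]] <- A
  for (i in seq_len(D)) {
    ABi <- A; ABi[, i] <- B[, i]
    blocks[[1L + i]] <- ABi
  }
  if (secondOrder) {
    for (i in seq_len(D)) {
      BAi <- B; BAi[, i] <- A[, i]
      blocks[[1L + D + i]] <- BAi
    }
  }
  blocks[[length(blocks)]] <- B
  U <- do.call(rbind, blocks)
  experimentalDesign(fromUnit(space, U), space, scheme = "saltelli",
                     seed = seed)
}

# split a Saltelli design's rows back into their blocks
saltelliBlocks <- function(n, D, secondOrder) {
  nb <- 2L + D + if (secondOrder) D else 0L
  stopifnot(n %% nb == 0)
  nBase <- n %/% nb
  idx <- function(b) (b - 1L) * nBase + seq_len(nBase)
  list(nBase = nBase,
       A = idx(1L),
       AB = lapply(seq_len(D), function(i) idx(1L + i)),
       BA = if (secondOrder) lapply(seq_len(D), function(i) idx(1L + D + i)),
       B = idx(nb))
}

#' Uniform rejection sampling under a predicate
#'
#' Draws uniform points in the box and keeps those satisfying \code{keep}
#' until \code{nTarget} points are accepted or \code{maxDraws} proposals are
#' spent. Used to sample the non-implausible (NROY) region, which has no
#' closed form.
#'
#' @param space a \linkS4class{ParameterSpace}.
#' @param keep deterministic predicate: a function taking an n x D matrix of
#'   points (physical units) and returning a logical vector.
#' @param nTarget number of accepted points requested.
#' @param seed integer seed.
#' @param maxDraws total proposal budget; when exhausted a partial design is
#'   returned with a warning and \code{exhausted = TRUE}.
#' @param batch proposals per iteration.
#' @return an \linkS4class{ExperimentalDesign} with scheme "rejection";
#'   the acceptance rate is recorded in the object.
#' @examples
#' d <- rejectionSample(defaultParameterSpace(), function(x) x[, "ap"] < 12, 50,
#'                      seed = 1)
#' @export
rejectionSample <- function(space, keep, nTarget, seed = 1L,
                            maxDraws = 1000L * nTarget, batch = 4096L) {
  nTarget <- as.integer(nTarget)
  if (is.na(nTarget) || nTarget < 1)
    ewStop("ew_design_error", "nTarget must be a positive count")
  D <- numParams(space)
  withSeed(seed, {
    kept <- matrix(numeric(0), 0, D)
    drawn <- 0L
    while (nrow(kept) < nTarget && drawn < maxDraws) {
      m <- min(batch, maxDraws - drawn, 2L * (nTarget - nrow(kept)))
      U <- matrix(runif(m * D), m, D)
      X <- fromUnit(space, U)
      ok <- as.logical(keep(X))
      kept <- rbind(kept, X[ok, , drop = FALSE])
      drawn <- drawn + m
    }
    accRate <- nrow(kept) / drawn
    exhausted <- nrow(kept) < nTarget
    if (exhausted)
      warning(sprintf(
        "rejection sampling exhausted %d draws with %d/%d accepted",
        drawn, nrow(kept), nTarget))
    if (nrow(kept) > nTarget) kept <- kept[seq_len(nTarget), , drop = FALSE]
    if (nrow(kept) == 0)
      ewStop("ew_design_error",
             "rejection sampling accepted no points within the draw budget")
    experimentalDesign(kept, space, scheme = "rejection", seed = seed,
                       acceptanceRate = accRate, exhausted = exhausted)
  })
}

#' Cloud augmentation of a point set under a predicate
#'
#' Generates new points satisfying \code{keep} by jittering existing ones:
#' each proposal perturbs a randomly chosen seed point with independent
#' per-dimension Gaussian noise of standard deviation
#' \code{jitterFrac * range}, clipped to the box. Proposals failing the
#' predicate are discarded. Used to repopulate a shrinking NROY cloud.
#'
#' @param seedPoints an \linkS4class{ExperimentalDesign} or point matrix of
#'   existing (keep-satisfying) points.
#' @param space a \linkS4class{ParameterSpace}; defaults to the design's.
#' @param keep predicate as in \code{\link{rejectionSample}}.
#' @param nTarget number of new points requested.
#' @param jitterFrac jitter SD as a fraction of each range, in (0, 1).
#' @param seed integer seed.
#' @param maxDraws total proposal budget.
#' @return an \linkS4class{ExperimentalDesign} with scheme "cloud" holding
#'   only the new points (the union with the seeds is duplicate-free).
#' @export
cloudAugment <- function(seedPoints, keep, nTarget, jitterFrac = 0.05,
                         seed = 1L, space = NULL,
                         maxDraws = 1000L * nTarget) {
  if (is(seedPoints, "ExperimentalDesign")) {
    if (is.null(space)) space <- seedPoints@space
    seedPoints <- designPoints(seedPoints)
  }
  if (is.null(space))
    ewStop("ew_design_error", "space required when seedPoints is a matrix")
  seedPoints <- asPointMatrix(space, seedPoints)
  if (nrow(seedPoints) == 0)
    ewStop("ew_design_error", "seedPoints must be non-empty")
  if (jitterFrac <= 0 || jitterFrac >= 1)
    ewStop("ew_design_error", "jitterFrac must be in (0, 1)")
  nTarget <- as.integer(nTarget)
  if (is.na(nTarget) || nTarget < 1)
    ewStop("ew_design_error", "nTarget must be a positive count")
  D <- numParams(space)
  sds <- jitterFrac * (space@upper - space@lower)
  withSeed(seed, {
    kept <- matrix(numeric(0), 0, D)
    drawn <- 0L
    batch <- max(1024L, 2L * nTarget)
    while (nrow(kept) < nTarget && drawn < maxDraws) {
      m <- min(batch, maxDraws - drawn)
      base <- seedPoints[sample.int(nrow(seedPoints), m, replace = TRUE), ,
                         drop = FALSE]
      prop <- base + matrix(rnorm(m * D), m, D) %*% diag(sds, D)
      prop <- pmin(pmax(prop, matrix(space@lower, m, D, byrow = TRUE)),
                   matrix(space@upper, m, D, byrow = TRUE))
      colnames(prop) <- space@names
      ok <- as.logical(keep(prop))
      kept <- rbind(kept, prop[ok, , drop = FALSE])
      drawn <- drawn + m
    }
    accRate <- nrow(kept) / drawn
    exhausted <- nrow(kept) < nTarget
    if (exhausted)
      warning(sprintf("cloud augmentation exhausted %d draws with %d/%d kept",
                      drawn, nrow(kept), nTarget))
    if (nrow(kept) > nTarget) kept <- kept[seq_len(nTarget), , drop = FALSE]
    kept <- kept[!duplicated(rbind(seedPoints, kept))[-seq_len(nrow(seedPoints))],
                 , drop = FALSE]
    if (nrow(kept) == 0)
      ewStop("ew_design_error",
             "cloud augmentation kept no points within the draw budget")
    experimentalDesign(kept, space, scheme = "cloud", seed = seed,
                       acceptanceRate = accRate, exhausted = exhausted)
  })
}

#' Write / read a design as CSV with a JSON sidecar
#'
#' The CSV holds one point per row under a header of parameter names; the
#' sidecar (same path with extension \code{.json}) records the scheme, the
#' seed and the space bounds so a design round-trips losslessly.
#'
#' @param design an \linkS4class{ExperimentalDesign}.
#' @param path CSV file path.
#' @return \code{writeDesign} returns \code{path} invisibly;
#'   \code{readDesign} returns the reconstructed design.
#' @export
writeDesign <- function(design, path) {
  write.csv(designPoints(design), path, row.names = FALSE)
  sp <- design@space
  jsonlite::write_json(
    list(scheme = design@scheme, seed = design@seed,
         names = sp@names, lower = sp@lower, upper = sp@upper,
         acceptanceRate = design@acceptanceRate,
         exhausted = design@exhausted),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDesign
#' @export
readDesign <- function(path) {
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path),
                                     ".json"), simplifyVector = TRUE)
  sp <- parameterSpace(meta$names, meta$lower, meta$upper)
  pts <- as.matrix(read.csv(path, check.names = FALSE))
  experimentalDesign(pts, sp, scheme = meta$scheme, seed = meta$seed,
                     acceptanceRate = meta$acceptanceRate,
                     exhausted = meta$exhausted)
}
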