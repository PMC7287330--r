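#' Construct a TargetSet
#'
#' @param features matched feature names (subset of the canonical twelve;
#'   EF is refused because it is derived from EDV and ESV).
#' @param mean observed means.
#' @param sd observation standard deviations (> 0).
#' @return a \linkS4class{TargetSet}.
#' @examples
#' targetSet(c("EDV", "PeakP"), c(230, 17), c(15, 1.5))
#' @export
targetSet <- function(features, mean, sd) {
  new("TargetSet", features = as.character(features), mean = as.numeric(mean),
      sd = as.numeric(sd))
}

#' Default matched-feature subset
#'
#' The seven organ-scale features conventionally constrained: volumes and
#' timings observable by imaging (EDV, ESV, ET, IVRT) plus pressure
#' magnitudes from the literature (PeakP, maxdP, mindP).
#'
#' @return character vector of length 7.
#' @export
matchedFeatures <- function() {
  c("EDV", "ESV", "ET", "IVRT", "PeakP", "maxdP", "mindP")
}

setMethod("show", "TargetSet", function(object) {
  cat("TargetSet with", length(object@features), "matched features\n")
  print(data.frame(mean = object@mean, sd = object@sd,
                   row.names = object@features))
})

#' Synthetic targets from a known ground-truth point
#'
#' Simulates the ground-truth parameter point, takes its features as the
#' underlying truth, and returns targets with means perturbed by seeded
#' observation noise and SDs set to a fraction of each feature magnitude.
#' Used for parameter-recovery experiments where the answer is known.
#'
#' @param mStar named parameter vector (must simulate with status "ok").
#' @param protocol a \linkS4class{SimProtocol}.
#' @param features matched subset (default \code{\link{matchedFeatures}}).
#' @param sdFrac observation SD as a fraction of each feature magnitude.
#' @param noise multiple of the SD used to perturb the target means
#'   (1 = typical observation error; 0 = noiseless targets).
#' @param seed integer seed for the perturbation.
#' @return list with the \code{targets} (\linkS4class{TargetSet}) and the
#'   noiseless \code{truth} feature vector.
#' @export
makeRecoveryTargets <- function(mStar, protocol = simProtocol(),
                                features = matchedFeatures(), sdFrac = 0.05,
                                noise = 1, seed = 1L) {
  tr <- simulateHeart(mStar, protocol)
  if (tr@status != "ok")
    ewStop("ew_hm_error", "ground-truth point must simulate successfully")
  f <- extractFeatures(tr)[features]
  sds <- sdFrac * abs(f)
  z <- f + noise * withSeed(seed, rnorm(length(f))) * sds
  list(targets = targetSet(features, z, sds), truth = f)
}

#' Implausibility of points under an emulator bank
#'
#' Per matched feature \code{I_i(x) = |z_i - mean_i(x)| /
#' sqrt(var_i(x) + sd_i^2)}; the score is the maximum over matched
#' features. No model-discrepancy term is included.
#'
#' @param bank an \linkS4class{EmulatorBank} covering all matched features.
#' @param targets a \linkS4class{TargetSet}.
#' @param X points in physical units (matrix or single point).
#' @param perFeature also return the feature-wise scores.
#' @return numeric vector of implausibility scores (or a list with
#'   \code{I} and the per-feature matrix when \code{perFeature}).
#' @examples
#' # I = 0.2 / sqrt(0.08^2 + 0.06^2) = 2 for a single matched feature
#' @export
implausibility <- function(bank, targets, X, perFeature = FALSE) {
  if (!all(targets@features %in% bankFeatures(bank)))
    ewStop("ew_hm_error", "every matched target needs an emulator")
  pr <- predictBank(bank, X)
  Im <- matrix(NA_real_, nrow(pr$mean), length(targets@features),
               dimnames = list(NULL, targets@features))
  for (j in seq_along(targets@features)) {
    fn <- targets@features[j]
    Im[, j] <- abs(targets@mean[j] - pr$mean[, fn]) /
      sqrt(pr$var[, fn] + targets@sd[j]^2)
  }
  I <- apply(Im, 1, max)
  if (perFeature) list(I = I, perFeature = Im) else I
}

# NROY membership test: max_i I_i(x) <= cutoff, evaluated feature by feature
# so that points already ruled out skip the remaining emulators; on large
# clouds a pilot subset orders the features by rejection power first
nroyMembership <- function(bank, targets, X, cutoff) {
  X <- asPointMatrix(bank@emulators[[1]]@space, X)
  n <- nrow(X)
  featOrder <- seq_along(targets@features)
  scoreOne <- function(j, P) {
    fn <- targets@features[j]
    pr <- predict(bank@emulators[[fn]], P)
    abs(targets@mean[j] - pr$mean) / sqrt(pr$var + targets@sd[j]^2)
  }
  if (n > 2000) {
    pilot <- X[seq_len(500), , drop = FALSE]
    rej <- vapply(featOrder, function(j) mean(scoreOne(j, pilot) > cutoff), 0)
    featOrder <- featOrder[order(-rej)]
  }
  alive <- rep(TRUE, n)
  for (j in featOrder) {
    if (!any(alive)) break
    alive[alive] <- scoreOne(j, X[alive, , drop = FALSE]) <= cutoff
  }
  alive
}

#' Implausibility cutoff schedule
#'
#' Starts at \code{start} in wave 1 and decreases by \code{step} per wave
#' until it reaches \code{floor}, where it stays.
#'
#' @param start starting cutoff (>= floor).
#' @param wave wave index (1-based); vectorised.
#' @param step decrement per wave.
#' @param floor final cutoff value.
#' @return cutoff value(s).
#' @examples
#' cutoffSchedule(5.5, 1:9)
#' @export
cutoffSchedule <- function(start, wave, step = 0.5, floor = 3.0) {
  if (start < floor) ewStop("ew_hm_error", "start must be >= floor")
  pmax(start - step * (wave - 1), floor)
}

#' Default desk-scale history-matching configuration
#'
#' Problem sizes small enough to run interactively: 20,000 initial test
#' points, 256 initial training simulations, 128 simulations and 5,000 new
#' test points per wave. \code{fullScale = TRUE} returns the full-scale
#' protocol (400,000 initial tests, 256 simulations and 50,000 new test
#' points per wave) used only for budget accounting.
#'
#' @param fullScale return the full-scale protocol sizes.
#' @return named list of configuration values.
#' @export
hmConfig <- function(fullScale = FALSE) {
  if (fullScale)
    list(nInitialTest = 400000L, nInitialTrain = 1024L, nSimPerWave = 256L,
         nNewPerWave = 50000L, cutoffStart = 5.5, cutoffStep = 0.5,
         cutoffFloor = 3.0, stopFraction = 0.001, maxWaves = 10L,
         jitterFrac = 0.05, gpRestarts = 5, gpMaxit = 60, cvFolds = 0L)
  else
    list(nInitialTest = 20000L, nInitialTrain = 256L, nSimPerWave = 128L,
         nNewPerWave = 5000L, cutoffStart = 5.0, cutoffStep = 0.5,
         cutoffFloor = 3.0, stopFraction = 0.001, maxWaves = 5L,
         jitterFrac = 0.05, gpRestarts = 2, gpMaxit = 50, cvFolds = 0L)
}

# internal: retrain the bank on the cumulative training table; when a
# previous bank is available its hyperparameters warm-start the fit and no
# cold restarts are added (the optimum moves little between waves)
retrainBank <- function(X, Y, space, targets, spec, config, seed,
                        prev = NULL) {
  inits <- NULL
  restarts <- config$gpRestarts
  maxit <- config$gpMaxit
  factr <- 1e9
  if (!is.null(prev)) {
    inits <- lapply(setNames(nm = targets@features), function(fn) {
      em <- prev[[fn]]
      list(lengthscales = em@lengthscales, sigf2 = em@sigf2,
           sign2 = em@sign2)
    })
    restarts <- 1
    maxit <- 15
    factr <- 1e11
  }
  trainEmulatorBank(X, Y = Y, space = space, features = targets@features,
                    specs = list(spec), cvFolds = config$cvFolds,
                    restarts = restarts, seed = seed,
                    maxit = maxit, factr = factr, inits = inits)
}

#' One history-matching wave
#'
#' Advances a wave state: draws \code{nSimPerWave} points uniformly (without
#' replacement) from the current NROY cloud, simulates them, appends the
#' successes to the cumulative training table, retrains the emulator bank,
#' assembles the next testing set (remaining NROY points plus
#' \code{nNewPerWave} new points generated inside the region by cloud
#' augmentation with rejection fallback), scores implausibility at the new
#' cutoff and shrinks NROY.
#'
#' @param state wave state list as produced by \code{\link{historyMatch}}
#'   internals: nroy, trainX, trainY, bank, wave, audit.
#' @param targets a \linkS4class{TargetSet}.
#' @param space the input \linkS4class{ParameterSpace}.
#' @param simulator batch runner: a function taking an n x D point matrix
#'   and returning a \code{SummarizedExperiment} as from
#'   \code{\link{simulateBatch}}.
#' @param config list from \code{\link{hmConfig}}.
#' @param spec emulator spec used for retraining.
#' @param seed integer seed for this wave.
#' @return updated state list with a \code{diag} record.
#' @keywords internal
runWave <- function(state, targets, space, simulator, config, spec, seed) {
  nroy <- state$nroy
  if (nrow(nroy) == 0)
    ewStop("ew_hm_error", "NROY region is empty; cannot run a wave")
  wave <- state$wave + 1L
  cutoff <- cutoffSchedule(config$cutoffStart, wave, config$cutoffStep,
                           config$cutoffFloor)
  nSim <- min(config$nSimPerWave, nrow(nroy))
  pick <- withSeed(childSeed(seed, 1), sample.int(nrow(nroy), nSim))
  simX <- nroy[pick, , drop = FALSE]
  rest <- nroy[-pick, , drop = FALSE]
  se <- simulator(simX)
  state$audit$simCalls <- state$audit$simCalls + nSim
  tv <- trainingView(se)
  if (nrow(tv$X) == 0)
    ewStop("ew_hm_error", "all wave simulations failed; state unchanged")
  trainX <- rbind(state$trainX, tv$X)
  trainY <- rbind(state$trainY, tv$Y)
  bank <- retrainBank(trainX, trainY, space, targets, spec, config,
                      childSeed(seed, 2), prev = state$bank)
  # new candidates inside the previous region (cloud with rejection fallback)
  prevBank <- state$bank
  prevCut <- state$cutoff
  keep <- function(P) nroyMembership(prevBank, targets, P, prevCut)
  newPts <- tryCatch(
    designPoints(cloudAugment(nroy, keep, config$nNewPerWave,
                              jitterFrac = config$jitterFrac,
                              seed = childSeed(seed, 3), space = space,
                              maxDraws = 20L * config$nNewPerWave)),
    ew_design_error = function(e)
      designPoints(rejectionSample(space, keep, config$nNewPerWave,
                                   seed = childSeed(seed, 4),
                                   maxDraws = 50L * config$nNewPerWave)))
  testX <- rbind(rest, newPts)
  keepIdx <- nroyMembership(bank, targets, testX, cutoff)
  state$audit$emuEvals <- state$audit$emuEvals + nrow(testX)
  state$nroy <- testX[keepIdx, , drop = FALSE]
  state$trainX <- trainX
  state$trainY <- trainY
  state$bank <- bank
  state$wave <- wave
  state$cutoff <- cutoff
  state$diag <- data.frame(
    wave = wave, cutoff = cutoff, nTest = nrow(testX),
    nNROY = sum(keepIdx), fracNROY = mean(keepIdx),
    nSimAttempted = nSim, nSimOk = nrow(tv$X), nTrain = nrow(trainX))
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wave-based Bayesian history matching
#'
#' Wave 1 trains emulators on an initial Latin hypercube of simulations and
#' scores a large initial LHD test cloud; subsequent waves simulate points
#' drawn from the surviving (NROY) cloud, retrain, rescore an augmented test
#' cloud at a decreasing implausibility cutoff, and shrink NROY. The run
#' stops when the non-implausible fraction falls below
#' \code{config$stopFraction}, when NROY empties, or at
#' \code{config$maxWaves}.
#'
#' @param space the input \linkS4class{ParameterSpace}.
#' @param targets a \linkS4class{TargetSet}.
#' @param protocol a \linkS4class{SimProtocol} for the default simulator.
#' @param config list from \code{\link{hmConfig}}.
#' @param spec emulator spec used per wave (degree, kernel).
#' @param seed master seed of the run.
#' @param simulator batch runner mapping an n x D point matrix to a
#'   \code{SummarizedExperiment}; defaults to the 0D heart simulator under
#'   \code{protocol}. Injectable so that cheap synthetic maps can drive the
#'   machinery.
#' @return a \linkS4class{HistoryMatchRun}.
#' @export
historyMatch <- function(space, targets, protocol = simProtocol(),
                         config = hmConfig(),
                         spec = list(degree = 2, kernel = "matern52"),
                         seed = 1L, simulator = NULL) {
  seed <- as.integer(seed)
  if (is.null(simulator))
    simulator <- function(X) simulateBatch(X, protocol, space = space)
  audit <- list(simCalls = 0, emuEvals = 0)
  # wave 1: train on an initial LHD, test the initial cloud
  dTrain <- latinHypercube(space, config$nInitialTrain, childSeed(seed, 101))
  se <- simulator(designPoints(dTrain))
  audit$simCalls <- audit$simCalls + designSize(dTrain)
  tv <- trainingView(se)
  if (nrow(tv$X) < 10)
    ewStop("ew_hm_error", "too few successful initial simulations")
  bank <- retrainBank(tv$X, tv$Y, space, targets, spec, config,
                      childSeed(seed, 102))
  dTest <- latinHypercube(space, config$nInitialTest, childSeed(seed, 103))
  testX <- designPoints(dTest)
  cutoff <- cutoffSchedule(config$cutoffStart, 1, config$cutoffStep,
                           config$cutoffFloor)
  member <- nroyMembership(bank, targets, testX, cutoff)
  audit$emuEvals <- audit$emuEvals + nrow(testX)
  nroy <- testX[member, , drop = FALSE]
  if (nrow(nroy) == 0)
    ewStop("ew_hm_error",
           "wave-1 NROY is empty; increase the starting cutoff")
  waves <- data.frame(
    wave = 1L, cutoff = cutoff, nTest = nrow(testX), nNROY = nrow(nroy),
    fracNROY = nrow(nroy) / nrow(testX),
    nSimAttempted = designSize(dTrain), nSimOk = nrow(tv$X),
    nTrain = nrow(tv$X))
  waves$cumVolFrac <- waves$fracNROY
  state <- list(nroy = nroy, trainX = tv$X, trainY = tv$Y, bank = bank,
                wave = 1L, cutoff = cutoff, audit = audit)
  while (state$wave < config$maxWaves) {
    if (waves$fracNROY[nrow(waves)] < config$stopFraction) break
    state <- runWave(state, targets, space, simulator, config, spec,
                     childSeed(seed, 200 + state$wave))
    state$diag$cumVolFrac <- waves$cumVolFrac[nrow(waves)] *
      state$diag$fracNROY
    waves <- rbind(waves, state$diag)
    if (nrow(state$nroy) == 0) {
      warning("NROY collapsed to empty; cutoff schedule may be too aggressive")
      break
    }
  }
  new("HistoryMatchRun", waves = waves, nroy = state$nroy,
      emulators = state$bank, space = space, targets = targets,
      cutoffFinal = state$cutoff, audit = state$audit, seed = seed)
}

setMethod("show", "HistoryMatchRun", function(object) {
  cat(sprintf(
    "HistoryMatchRun: %d waves, final cutoff %.1f, %d NROY points\n",
    nrow(object@waves), object@cutoffFinal, nrow(object@nroy)))
  print(object@waves, row.names = FALSE)
  cat(sprintf("audit: %d simulator calls, %d emulator point-evaluations\n",
              as.integer(object@audit$simCalls),
              as.integer(object@audit$emuEvals)))
})

#' Per-dimension NROY ranges, normalised to the initial box
#'
#' @param points NROY point matrix (or a \linkS4class{HistoryMatchRun}).
#' @param space the initial \linkS4class{ParameterSpace}; taken from the run
#'   when a run is given.
#' @return data.frame with min, max and the retained fraction of each
#'   initial range.
#' @export
nroyRanges <- function(points, space = NULL) {
  if (is(points, "HistoryMatchRun")) {
    space <- points@space
    points <- points@nroy
  }
  if (is.null(space)) ewStop("ew_hm_error", "space required")
  if (nrow(points) == 0) ewStop("ew_hm_error", "empty point set")
  points <- asPointMatrix(space, points)
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  data.frame(parameter = space@names, min = lo, max = hi,
             fracOfInitial = (hi - lo) / (space@upper - space@lower),
             row.names = NULL)
}

#' Overlap of two NROY runs, per dimension
#'
#' Compares the one-dimensional envelopes of two runs (e.g. two phenotypes)
#' on the shared initial box; the overlap is empty when the envelopes are
#' disjoint in a dimension.
#'
#' @param run1,run2 \linkS4class{HistoryMatchRun}s sharing a space (or point
#'   matrices with \code{space} given).
#' @param space required for bare matrices.
#' @return data.frame with both ranges and the overlap (NA when empty),
#'   normalised widths included.
#' @export
nroyOverlap <- function(run1, run2, space = NULL) {
  r1 <- nroyRanges(run1, space)
  r2 <- nroyRanges(run2, space)
  lo <- pmax(r1$min, r2$min)
  hi <- pmin(r1$max, r2$max)
  empty <- lo > hi
  data.frame(parameter = r1$parameter,
             min1 = r1$min, max1 = r1$max, min2 = r2$min, max2 = r2$max,
             overlapMin = ifelse(empty, NA_real_, lo),
             overlapMax = ifelse(empty, NA_real_, hi),
             separated = empty, row.names = NULL)
}

#' Exact simulator/emulator budget of a wave protocol
#'
#' Protocol accounting: across one or more runs, the simulator is called
#' \code{nWaves * nSimPerWave} times per run (every wave, including the
#' initial ones, simulates a training batch) and the emulators are evaluated
#' over the initial test cloud once plus \code{nNewPerWave} new test points
#' in every wave after the first.
#'
#' @param nInitialTest initial test-cloud size(s), one per run.
#' @param nWaves total wave count(s), one per run.
#' @param nSimPerWave simulations per wave.
#' @param nNewPerWave new test points per post-initial wave.
#' @return list with \code{simulations} and \code{emulatorEvaluations}.
#' @examples
#' hmBudget(c(400000, 400000), c(8, 9), 256, 50000)
#' @export
hmBudget <- function(nInitialTest, nWaves, nSimPerWave, nNewPerWave) {
  k <- max(length(nInitialTest), length(nWaves))
  nInitialTest <- rep_len(nInitialTest, k)
  nWaves <- rep_len(nWaves, k)
  nSimPerWave <- rep_len(nSimPerWave, k)
  nNewPerWave <- rep_len(nNewPerWave, k)
  list(simulations = sum(nWaves * nSimPerWave),
       emulatorEvaluations = sum(nInitialTest +
                                   pmax(nWaves - 1, 0) * nNewPerWave))
}
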