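test_that("implausibility matches its hand-computed definition", {
  # one matched feature: z = 1.0, sd_obs = 0.06, emulator mean 1.2, sd 0.08
  # I = |1.0 - 1.2| / sqrt(0.08^2 + 0.06^2) = 0.2 / 0.1 = 2
  sp <- toySpace()
  em <- new("GPEmulator", featureName = "PeakP", kernel = "matern52",
            degree = 1, beta = c(1.2, 0, 0), lengthscales = c(1e-2, 1e-2),
            sigf2 = 0.0064, sign2 = 0, logLik = 0, space = sp,
            Xunit = matrix(c(-50, -50), 1, 2), resid = 0, alpha = 0,
            L = matrix(0.08, 1, 1), Kinv = matrix(1 / 0.0064, 1, 1),
            yCenter = 0, yScale = 1, cvR2 = NA_real_)
  bank <- new("EmulatorBank", emulators = list(PeakP = em))
  tg <- targetSet("PeakP", 1.0, 0.06)
  x <- matrix(0.5, 1, 2, dimnames = list(NULL, c("p", "ap")))
  expect_equal(implausibility(bank, tg, x), 2, tolerance = 1e-6)
  # perfect match scores zero
  tg0 <- targetSet("PeakP", 1.2, 0.06)
  expect_equal(implausibility(bank, tg0, x), 0, tolerance = 1e-6)
  # huge emulator variance makes a feature impossible to rule out
  emWide <- em
  emWide@sigf2 <- 1e8
  emWide@Kinv <- matrix(1e-8, 1, 1)
  bankW <- new("EmulatorBank", emulators = list(PeakP = emWide))
  expect_lt(implausibility(bankW, tg, x), 1e-3)
  # missing emulator for a matched target is a typed error
  tg2 <- targetSet(c("PeakP", "EDV"), c(1, 2), c(0.1, 0.1))
  expect_error(implausibility(bank, tg2, x), class = "ew_hm_error")
})

test_that("target sets refuse EF and non-positive spreads", {
  expect_error(targetSet("EF", 60, 5))
  expect_error(targetSet("PeakP", 17, 0))
  expect_error(targetSet("NotAFeature", 1, 1))
  expect_length(matchedFeatures(), 7)
  expect_false("EF" %in% matchedFeatures())
})

test_that("the cutoff schedule decreases by steps to its floor", {
  expect_equal(cutoffSchedule(5.5, 1), 5.5)
  expect_equal(cutoffSchedule(5.5, 2), 5.0)
  expect_equal(cutoffSchedule(5.5, 1:9),
               c(5.5, 5.0, 4.5, 4.0, 3.5, 3.0, 3.0, 3.0, 3.0))
  expect_equal(cutoffSchedule(5.0, 9), 3.0)
  expect_error(cutoffSchedule(2.0, 1), class = "ew_hm_error")
})

test_that("budget accounting reproduces exact protocol totals", {
  b <- hmBudget(c(400000, 400000), c(8, 9), 256, 50000)
  expect_identical(b$simulations, 4352)
  expect_identical(b$emulatorEvaluations, 1550000)
  expect_equal(hmBudget(1000, 0, 256, 500)$simulations, 0)
  b1 <- hmBudget(20000, 5, 128, 5000)
  expect_equal(b1$simulations, 640)
  expect_equal(b1$emulatorEvaluations, 20000 + 4 * 5000)
})

test_that("history matching shrinks a toy NROY space onto the truth", {
  sp <- toySpace()
  sim <- makeToySimulator(sp, toyFuncs)
  mStar <- c(p = 0.35, ap = 0.6)
  truth <- vapply(toyFuncs, function(f) f(matrix(mStar, 1)), 0)
  tg <- targetSet(names(truth), truth, 0.03 * abs(truth))
  cfg <- hmConfig()
  cfg$nInitialTest <- 2000L
  cfg$nInitialTrain <- 40L
  cfg$nSimPerWave <- 20L
  cfg$nNewPerWave <- 500L
  cfg$maxWaves <- 3L
  run <- historyMatch(sp, tg, config = cfg, seed = 5, simulator = sim)
  expect_s4_class(run, "HistoryMatchRun")
  expect_equal(nrow(run@waves), 3L)
  # cutoffs follow the schedule and never increase
  expect_equal(run@waves$cutoff, c(5.0, 4.5, 4.0))
  # training table strictly grows
  expect_true(all(diff(run@waves$nTrain) > 0))
  # cumulative NROY volume fraction decreases strictly
  expect_true(all(diff(run@waves$cumVolFrac) < 0))
  # the truth stays non-implausible and NROY points satisfy the cut
  expect_lte(implausibility(run@emulators, tg, mStar), run@cutoffFinal)
  Invar <- implausibility(run@emulators, tg, run@nroy)
  expect_true(all(Invar <= run@cutoffFinal + 1e-8))
  # audit log conservation
  expect_equal(run@audit$simCalls,
               cfg$nInitialTrain + 2 * cfg$nSimPerWave)
  expect_equal(run@audit$emuEvals, sum(run@waves$nTest))
})

test_that("degenerate stop rules and failure modes are typed", {
  sp <- toySpace()
  sim <- makeToySimulator(sp, toyFuncs)
  mStar <- c(p = 0.35, ap = 0.6)
  truth <- vapply(toyFuncs, function(f) f(matrix(mStar, 1)), 0)
  tg <- targetSet(names(truth), truth, 0.05 * abs(truth))
  cfg <- hmConfig()
  cfg$nInitialTest <- 500L
  cfg$nInitialTrain <- 30L
  cfg$stopFraction <- 1.0
  cfg$maxWaves <- 4L
  run <- historyMatch(sp, tg, config = cfg, seed = 2, simulator = sim)
  expect_equal(nrow(run@waves), 1L)  # stops right after wave 1

  # unreachable targets empty the wave-1 NROY with a typed error
  tgBad <- targetSet(names(truth), truth + 1e4, 0.001 * abs(truth))
  expect_error(historyMatch(sp, tgBad, config = cfg, seed = 2,
                            simulator = sim),
               class = "ew_hm_error")

  # all wave simulations failing aborts the wave with a typed error
  nCalls <- 0L
  simFail <- function(X) {
    nCalls <<- nCalls + 1L
    makeToySimulator(sp, toyFuncs,
                     failWhen = if (nCalls > 1)
                       function(P) rep(TRUE, nrow(P)))(X)
  }
  cfg$stopFraction <- 0
  expect_error(historyMatch(sp, tg, config = cfg, seed = 2,
                            simulator = simFail),
               class = "ew_hm_error")
})

test_that("NROY ranges are normalised to the initial box", {
  sp <- toySpace()
  full <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  colnames(full) <- paramNames(sp)
  r <- nroyRanges(full, sp)
  expect_equal(r$fracOfInitial, c(1, 1))
  single <- matrix(c(0.3, 0.4), 1, dimnames = list(NULL, paramNames(sp)))
  rs <- nroyRanges(single, sp)
  expect_equal(rs$fracOfInitial, c(0, 0))
  expect_error(nroyRanges(full[0, , drop = FALSE], sp),
               class = "ew_hm_error")
  # disjoint clouds report an empty overlap in the separated dimension
  a <- matrix(c(0.1, 0.2, 0.5, 0.6), 2, 2,
              dimnames = list(NULL, paramNames(sp)))
  b <- matrix(c(0.7, 0.9, 0.5, 0.6), 2, 2,
              dimnames = list(NULL, paramNames(sp)))
  ov <- nroyOverlap(a, b, sp)
  expect_true(ov$separated[1])
  expect_false(ov$separated[2])
  expect_true(is.na(ov$overlapMin[1]))
})

test_that("recovery targets are reproducible and centred on the truth", {
  space <- defaultParameterSpace()
  mid <- setNames((lowerBounds(space) + upperBounds(space)) / 2,
                  paramNames(space))
  rt1 <- makeRecoveryTargets(mid, seed = 3)
  rt2 <- makeRecoveryTargets(mid, seed = 3)
  expect_identical(rt1$targets@mean, rt2$targets@mean)
  expect_equal(rt1$targets@sd, 0.05 * abs(rt1$truth), ignore_attr = TRUE)
  expect_true(all(abs(rt1$targets@mean - rt1$truth) < 4 * rt1$targets@sd))
  rt0 <- makeRecoveryTargets(mid, noise = 0, seed = 3)
  expect_equal(rt0$targets@mean, rt0$truth, ignore_attr = TRUE)
})
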