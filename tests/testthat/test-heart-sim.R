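proto <- simProtocol()
space <- defaultParameterSpace()
mid <- setNames((lowerBounds(space) + upperBounds(space)) / 2,
                paramNames(space))

test_that("calcium transient has the prescribed pulse shape", {
  expect_equal(calciumTransient(0, proto), proto@caDia)
  # stationary point: peak value caDia + caAmp exactly at t = tau
  expect_equal(calciumTransient(proto@caTau, proto),
               proto@caDia + proto@caAmp)
  eps <- 1e-4
  expect_lt(calciumTransient(proto@caTau + eps, proto),
            calciumTransient(proto@caTau, proto))
  # long-tail decay: at 5 tau the pulse is below 20% of its amplitude
  expect_lt(calciumTransient(5 * proto@caTau, proto) - proto@caDia,
            0.2 * proto@caAmp)
  # periodicity across beats
  expect_equal(calciumTransient(cycleLength(proto) + 3, proto),
               calciumTransient(3, proto))
})

test_that("mid-range point ejects with ordered valve events", {
  tr <- simulateHeart(mid, proto)
  expect_equal(tr@status, "ok")
  ev <- tr@events
  expect_true(all(is.finite(ev)))
  expect_true(ev[["mitral_close"]] <= ev[["aortic_open"]])
  expect_true(ev[["aortic_open"]] <= ev[["aortic_close"]])
  expect_true(ev[["aortic_close"]] <= ev[["mitral_open"]])
  expect_gt(max(tr@pressure), mid[["ap"]])
  expect_true(all(tr@volume > 0))
  f <- extractFeatures(tr)
  expect_gt(f[["EF"]], 50)
  expect_lt(f[["EF"]], 80)
})

test_that("vanishing active force cannot reach the aortic pressure", {
  weak <- mid
  weak[["Tref"]] <- 0.01
  expect_equal(simulateHeart(weak, proto)@status, "no_ejection")
})

test_that("paired parameter perturbations move features monotonically", {
  f0 <- extractFeatures(simulateHeart(mid, proto))
  pert <- function(nm, fac) {
    m <- mid
    m[[nm]] <- m[[nm]] * fac
    extractFeatures(simulateHeart(m, proto))
  }
  expect_gt(pert("Tref", 1.3)[["PeakP"]], f0[["PeakP"]])  # more force
  expect_lt(pert("c1", 1.4)[["EDV"]], f0[["EDV"]])        # stiffer wall
  expect_lt(pert("ca50", 1.4)[["PeakP"]], f0[["PeakP"]])  # less Ca-sensitive
})

test_that("ejected volume matches the aortic flow integral", {
  tr <- simulateHeart(mid, proto)
  f <- extractFeatures(tr)
  sv <- f[["EDV"]] - f[["ESV"]]
  expect_lt(abs(sv - tr@flowIntegral) / sv, 0.005)
})

test_that("simulation is deterministic and batches encode failures as data", {
  tr1 <- simulateHeart(mid, proto)
  tr2 <- simulateHeart(mid, proto)
  expect_identical(tr1@pressure, tr2@pressure)
  expect_identical(tr1@events, tr2@events)

  d <- latinHypercube(space, 48, seed = 21)
  se <- simulateBatch(d, proto)
  expect_equal(ncol(se), 48L)
  expect_equal(nrow(se), 12L)
  cnt <- S4Vectors::metadata(se)$counts
  expect_equal(sum(cnt), 48)
  feats <- SummarizedExperiment::assay(se, "features")
  failed <- se$status != "ok"
  if (any(failed)) expect_true(all(is.na(feats[, failed])))
  expect_true(all(!is.na(feats[, !failed])))
  tv <- trainingView(se)
  expect_equal(nrow(tv$X), as.integer(cnt[["ok"]]))
  # byte-identical rerun
  se2 <- simulateBatch(d, proto)
  expect_identical(feats, SummarizedExperiment::assay(se2, "features"))

  # constant design at a known-good point: all ok, identical features
  ctr <- matrix(rep(mid, 3), 3, byrow = TRUE,
                dimnames = list(NULL, names(mid)))
  se3 <- simulateBatch(ctr, proto)
  expect_true(all(se3$status == "ok"))
  f3 <- SummarizedExperiment::assay(se3, "features")
  expect_equal(f3[, 1], f3[, 2])
  expect_equal(f3[, 1], f3[, 3])
})

test_that("GSA benchmark functions evaluate exactly", {
  expect_equal(ishigami(c(0, 0, 0)), 0)
  expect_equal(ishigami(c(pi / 2, 0, 0), a = 7, b = 0), 1)
  x <- c(0.3, -1.2, 2.0)
  expect_equal(ishigami(x, 7, 0.1),
               sin(x[1]) + 7 * sin(x[2])^2 + 0.1 * x[3]^4 * sin(x[1]))
  a <- c(0, 1, 4.5, 9)
  expect_equal(sobolG(rep(0.5, 4), a), 0)       # |4*0.5-2| = 0, a1 = 0
  expect_equal(sobolG(rep(0.5, 4), a + 1), prod((a + 1) / (a + 2)))
  big <- rep(1e6, 4)
  expect_lt(abs(sobolG(runif(4), big) - 1), 1e-5)
})
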