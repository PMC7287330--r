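spIshi <- parameterSpace(c("x1", "x2", "x3"), rep(-pi, 3), rep(pi, 3))

test_that("additive functions have equal first-order and no interaction", {
  spAdd <- parameterSpace(paste0("x", 1:4), rep(0, 4), rep(1, 4))
  res <- sobolIndices(function(X) rowSums(X), spAdd, nBase = 2^12, seed = 3)
  expect_true(all(abs(res@S1 - 0.25) < 0.01))
  expect_true(all(abs(res@ST - 0.25) < 0.01))
  expect_true(all(abs(res@S2[upper.tri(res@S2)]) < 0.01))
  expect_lt(abs(res@higherOrder), 0.03)
})

test_that("Ishigami indices converge to their closed-form values", {
  # analytic oracle (a = 7, b = 0.1):
  # V = a^2/8 + b pi^4/5 + b^2 pi^8/18 + 1/2
  S1true <- c(0.31390519, 0.44241114, 0)
  STtrue <- c(0.55758886, 0.44241114, 0.24368366)
  S13true <- 0.24368366
  resLo <- sobolIndices(ishigami, spIshi, nBase = 2^11, seed = 5)
  expect_true(all(abs(resLo@S1 - S1true) < 0.05))
  res <- sobolIndices(ishigami, spIshi, nBase = 2^14, seed = 5)
  expect_true(all(abs(res@S1 - S1true) < 0.02))
  expect_true(all(abs(res@ST - STtrue) < 0.02))
  expect_lt(abs(res@S2[1, 3] - S13true), 0.02)
  expect_lt(abs(res@S2[1, 2]), 0.02)
  # estimator error shrinks with the sample size
  errLo <- max(abs(resLo@S1 - S1true))
  errHi <- max(abs(res@S1 - S1true))
  expect_lt(errHi, errLo + 0.01)
})

test_that("g-function indices match their closed form", {
  a <- c(0, 1, 4.5, 9)
  spG <- parameterSpace(paste0("x", 1:4), rep(0, 4), rep(1, 4))
  S1true <- c(0.71649293, 0.17912323, 0.02368572, 0.00716493)
  STtrue <- c(0.78736970, 0.24226760, 0.03432674, 0.01046338)
  res <- sobolIndices(function(X) sobolG(X, a), spG, nBase = 2^14, seed = 2)
  expect_true(all(abs(res@S1 - S1true) < 0.02))
  expect_true(all(abs(res@ST - STtrue) < 0.02))
  # package closed-form helper agrees with the frozen oracle values
  cf <- sobolGIndices(a)
  expect_equal(cf$S1, S1true, tolerance = 1e-6)
  expect_equal(cf$ST, STtrue, tolerance = 1e-6)
})

test_that("degenerate outputs and determinism are handled", {
  expect_error(sobolIndices(function(X) rep(1, nrow(X)), spIshi,
                            nBase = 256),
               class = "ew_gsa_error")
  r1 <- sobolIndices(ishigami, spIshi, nBase = 1024, seed = 9)
  r2 <- sobolIndices(ishigami, spIshi, nBase = 1024, seed = 9)
  expect_identical(r1@S1, r2@S1)
  expect_identical(r1@S2, r2@S2)
  # total effects dominate first-order effects up to estimator noise
  expect_true(all(r1@ST >= r1@S1 - 0.02))
})

test_that("stacked aggregation attributes interactions and clips noise", {
  spAdd <- parameterSpace(paste0("x", 1:3), rep(0, 3), rep(1, 3))
  resAdd <- sobolIndices(function(X) rowSums(X), spAdd, nBase = 2^12,
                         seed = 1)
  agg <- aggregateContributions(resAdd)
  # additive: stacks reduce to the first-order effects, remainder ~ 0
  expect_true(all(abs(agg$stack$share - pmax(resAdd@S1, 0)) < 0.02))
  expect_lt(agg$higherOrder[["display"]], 0.05)
  expect_true(all(agg$stack$share >= 0))
  expect_true(all(agg$pairs$S2 >= 0))             # clipped for display
  expect_equal(agg$pairs$S2, pmax(agg$pairs$S2raw, 0))  # raw kept alongside

  resI <- sobolIndices(ishigami, spIshi, nBase = 2^13, seed = 4)
  aggI <- aggregateContributions(resI)
  p13 <- aggI$pairs[aggI$pairs$i == "x1" & aggI$pairs$j == "x3", ]
  expect_gt(p13$S2, 0.2)                   # the (1,3) interaction is real
  expect_lt(abs(aggI$higherOrder[["raw"]]), 0.05)  # no third-order term
})

test_that("a shared design drives a whole emulator bank", {
  sp <- toySpace()
  sim <- makeToySimulator(sp, toyFuncs)
  X <- designPoints(latinHypercube(sp, 60, seed = 2))
  se <- sim(X)
  bank <- trainEmulatorBank(se, specs = list(list(degree = 2,
                                                  kernel = "matern52")),
                            cvFolds = 0, restarts = 3, seed = 5)
  out <- sobolBank(bank, sp, nBase = 2^10, seed = 6)
  expect_length(out, 2)
  expect_s4_class(out$EDV, "SobolResult")
  # EDV is driven more by p (linear, strong) than PeakP is by ap
  expect_gt(out$EDV@S1[["p"]], out$EDV@S1[["ap"]])
  out2 <- sobolBank(bank, sp, nBase = 2^10, seed = 6)
  expect_identical(out$EDV@S1, out2$EDV@S1)
})
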