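test_that("Latin hypercube designs stratify every dimension exactly once", {
  sp <- parameterSpace(c("a", "b"), c(-2, 10), c(4, 20))
  d <- latinHypercube(sp, 16, seed = 3)
  P <- designPoints(d)
  expect_equal(dim(P), c(16L, 2L))
  for (j in 1:2) {
    strata <- findInterval(P[, j],
                           seq(sp@lower[j], sp@upper[j], length.out = 17),
                           rightmost.closed = TRUE)
    expect_equal(sort(strata), 1:16)  # one point per stratum
  }
  # degenerate n = 1 still lies inside the box
  d1 <- latinHypercube(sp, 1, seed = 5)
  expect_true(all(designPoints(d1) >= sp@lower & designPoints(d1) <= sp@upper))
  expect_error(latinHypercube(sp, 0), class = "ew_design_error")
})

test_that("designs are bit-reproducible for a fixed seed", {
  sp <- defaultParameterSpace()
  expect_identical(designPoints(latinHypercube(sp, 50, seed = 7)),
                   designPoints(latinHypercube(sp, 50, seed = 7)))
  expect_false(identical(designPoints(latinHypercube(sp, 50, seed = 7)),
                         designPoints(latinHypercube(sp, 50, seed = 8))))
  expect_identical(designPoints(saltelliDesign(sp, 16, seed = 2)),
                   designPoints(saltelliDesign(sp, 16, seed = 2)))
})

test_that("Saltelli designs have the exact block row counts", {
  sp8 <- defaultParameterSpace()
  expect_equal(designSize(saltelliDesign(sp8, 1024, secondOrder = TRUE)),
               1024 * (2 * 8 + 2))  # 18432
  sp2 <- parameterSpace(c("x", "y"), c(0, 0), c(1, 1))
  expect_equal(designSize(saltelliDesign(sp2, 8, secondOrder = FALSE)),
               8 * (2 + 2))
  expect_error(saltelliDesign(sp2, 12), class = "ew_design_error")  # not 2^k
  expect_error(saltelliDesign(sp2, 0), class = "ew_design_error")
})

test_that("Saltelli base matrices are low-discrepancy uniform", {
  sp3 <- parameterSpace(c("x", "y", "z"), rep(0, 3), rep(1, 3))
  d <- saltelliDesign(sp3, 1024, secondOrder = FALSE, seed = 4)
  P <- designPoints(d)
  # A block occupies the first nBase rows
  expect_true(all(abs(colMeans(P[1:1024, ]) - 0.5) < 0.01))
  expect_true(all(abs(colMeans(P[(nrow(P) - 1023):nrow(P), ]) - 0.5) < 0.01))
})

test_that("rejection sampling honours its predicate and reports acceptance", {
  sp <- parameterSpace(c("u", "v"), c(0, 0), c(1, 1))
  dAll <- rejectionSample(sp, function(X) rep(TRUE, nrow(X)), 100, seed = 1)
  expect_equal(designSize(dAll), 100L)
  expect_equal(dAll@acceptanceRate, 1)

  half <- function(X) X[, 1] < 0.5
  dHalf <- rejectionSample(sp, half, 2000, seed = 2)
  expect_true(all(half(designPoints(dHalf))))
  expect_gt(dHalf@acceptanceRate, 0.45)
  expect_lt(dHalf@acceptanceRate, 0.55)

  # exhausted budget returns a partial design with a warning flag
  rare <- function(X) X[, 1] < 0.01
  expect_warning(
    dRare <- rejectionSample(sp, rare, 500, seed = 3, maxDraws = 2000),
    "exhausted")
  expect_true(dRare@exhausted)
  expect_lt(designSize(dRare), 500L)
  expect_true(all(rare(designPoints(dRare))))
})

test_that("cloud augmentation jitters inside the box and re-checks keep", {
  sp <- parameterSpace(c("u", "v"), c(0, 0), c(1, 1))
  seeds <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("u", "v")))
  d <- cloudAugment(seeds, function(X) rep(TRUE, nrow(X)), 100, seed = 1,
                    space = sp)
  expect_equal(designSize(d), 100L)
  expect_true(all(designPoints(d) >= 0 & designPoints(d) <= 1))

  # keep-region membership is preserved by construction
  inBall <- function(X) rowSums((X - 0.5)^2) < 0.2^2
  ctr <- matrix(0.5, 5, 2, dimnames = list(NULL, c("u", "v")))
  dB <- cloudAugment(ctr, inBall, 50, jitterFrac = 0.1, seed = 2, space = sp)
  expect_true(all(inBall(designPoints(dB))))

  # tiny jitter: proposals stay arbitrarily close to their seed points
  dT <- cloudAugment(ctr, function(X) rep(TRUE, nrow(X)), 20,
                     jitterFrac = 1e-6, seed = 3, space = sp)
  expect_true(all(abs(designPoints(dT) - 0.5) < 1e-4))

  expect_error(cloudAugment(seeds[0, , drop = FALSE], inBall, 10, space = sp),
               class = "ew_design_error")
  expect_error(cloudAugment(seeds, inBall, 10, jitterFrac = 1.5, space = sp),
               class = "ew_design_error")
})

test_that("parameter space validity and unit conversion hold", {
  expect_error(parameterSpace(c("a", "a"), c(0, 0), c(1, 1)))
  expect_error(parameterSpace(c("a", "b"), c(0, 2), c(1, 1)))
  expect_equal(mmHgSecPerMl2kPaMsPerUl(1), 0.133322)
  expect_equal(mmHgSecPerMl2kPaMsPerUl(7.5), 7.5 * 0.133322)
  sp <- defaultParameterSpace()
  expect_equal(numParams(sp), 8L)
  expect_equal(paramNames(sp)[1], "p")
  expect_equal(paramNames(sp)[8], "Tref")
})

test_that("designs round-trip through CSV plus JSON sidecar", {
  sp <- defaultParameterSpace()
  d <- latinHypercube(sp, 20, seed = 9)
  path <- tempfile(fileext = ".csv")
  writeDesign(d, path)
  d2 <- readDesign(path)
  expect_equal(designPoints(d2), designPoints(d), tolerance = 1e-12)
  expect_equal(d2@scheme, "lhd")
  expect_equal(d2@seed, 9L)
  expect_equal(paramNames(d2@space), paramNames(sp))
})
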