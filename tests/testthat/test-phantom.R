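test_that("vessel tree base case is one trunk tube per lung compartment", {
  spec <- phantomSpec(vesselLevels = 1L)
  v <- generateVesselTree(spec, seed = 3)
  cc <- perfusionBSN:::connectedComponents3D(v)
  expect_identical(length(cc$sizes), 2L)  # one tree per lung
  expect_true(all(cc$sizes > 0))
  counts <- attr(v, "levelCounts")
  expect_identical(length(counts), 1L)
  expect_identical(sum(v), as.integer(sum(counts)))
})

test_that("vessel tree is deterministic given the seed", {
  spec <- phantomSpec()
  v1 <- generateVesselTree(spec, seed = 11)
  v2 <- generateVesselTree(spec, seed = 11)
  v3 <- generateVesselTree(spec, seed = 12)
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
})

test_that("per-level vessel voxel counts decrease with branching level", {
  spec <- phantomSpec(gridShape = c(16L, 64L, 64L), vesselLevels = 4L)
  v <- generateVesselTree(spec, seed = 5)
  counts <- attr(v, "levelCounts")
  expect_identical(length(counts), 4L)
  expect_true(all(diff(counts) < 0))
})

test_that("excessive branching depth stops at sub-voxel radii with warning", {
  spec <- phantomSpec(vesselLevels = 9L)
  expect_warning(generateVesselTree(spec, seed = 1), "sub-voxel")
})

test_that("zero enhancement curve reproduces static anatomy at every frame", {
  spec <- phantomSpec(enhancementCurve = rep(0, 4), nTimepoints = 4L)
  b <- generatePhantom(spec, seed = 2)
  dat <- seriesData(cleanSeries(b))
  for (t in 2:4) expect_equal(dat[t, , , ], dat[1, , , ])
})

test_that("peak curve frame has the largest lung-mean intensity", {
  spec <- phantomSpec(enhancementCurve = c(0, 0.5, 1, 0.5), nTimepoints = 4L)
  b <- generatePhantom(spec, seed = 2)
  m <- lungMask(b) > 0
  lungMeans <- apply(seriesData(cleanSeries(b)), 1, function(v) mean(v[m]))
  expect_identical(which.max(lungMeans), 3L)
})

test_that("a full perfusion deficit suppresses all enhancement in the lesion", {
  spec <- phantomSpec(lesion = list(center = c(6, 30, 20), radius = 5,
                                    deficit = 1.0))
  b <- generatePhantom(spec, seed = 2)
  les <- perfusionBSN:::ellipsoidMask(spec@gridShape, c(6, 30, 20), rep(5, 3))
  dat <- seriesData(cleanSeries(b))
  for (t in seq_len(spec@nTimepoints))
    expect_equal(dat[t, , , ][les], dat[1, , , ][les])
  # enhancement elsewhere still present at the peak
  expect_gt(max(dat[4, , , ] - dat[1, , , ]), 0)
})

test_that("noise is reproducible and zero-mean where clipping cannot bind", {
  b1 <- getPhantom(noiseSeed = 1L)
  b2 <- simulatePhantom(phantomSpec(), noiseSpec(seed = 1L), seed = 1L)
  expect_identical(seriesData(noisySeries(b1)), seriesData(noisySeries(b2)))
  d <- seriesData(noisySeries(b1)) - seriesData(cleanSeries(b1))
  body <- seriesData(cleanSeries(b1))[1, , , ] >= 60  # sigma = 20 << 60
  resid <- apply(d, 1, function(v) mean(v[body]))
  expect_true(all(abs(resid) < 1))  # mean of ~30k draws of sd 20-30
})

test_that("local noise sd matches baseSigma times the gain field within 5%", {
  b <- getPhantom(noiseSeed = 3L)
  d <- seriesData(noisySeries(b)) - seriesData(cleanSeries(b))
  gain <- perfusionBSN:::gainField(64, 64, 0.5)
  # central window: near-uniform gain, clean intensity >> sigma (no clipping)
  w <- 23:42
  samp <- d[, , w, w]  # 6 t x 12 slices x 20 x 20 = 28800 pixels
  expected <- 20 * mean(gain[w, w])
  expect_lt(abs(stats::sd(samp) - expected) / expected, 0.05)
})

test_that("white noise is uncorrelated; smoothed noise matches its kernel", {
  clean <- dynamicSeries(array(500, c(2, 4, 64, 64)))
  lag1cor <- function(m, lag = 1)
    stats::cor(as.vector(m[1:(nrow(m) - lag), ]),
               as.vector(m[(1 + lag):nrow(m), ]))
  nw <- applyNoise(clean, noiseSpec(correlationFwhm = 0, seed = 5))
  dw <- seriesData(nw)[1, 1, , ] - 500
  expect_lt(abs(lag1cor(dw)), 0.05)

  ns <- applyNoise(clean, noiseSpec(correlationFwhm = 4, seed = 5))
  ds <- seriesData(ns)[1, 1, , ] - 500
  # oracle: autocorrelation of the smoothing kernel computed numerically
  sig <- 4 / (2 * sqrt(2 * log(2)))
  k <- perfusionBSN:::gaussianKernel1D(sig)
  rho1 <- sum(k[-1] * k[-length(k)]) / sum(k^2)
  expect_gt(lag1cor(ds), 0.4)
  expect_lt(abs(lag1cor(ds) - rho1), 0.1)
  # lag-10 pooled over all frames/slices: beyond the kernel support
  dAll <- seriesData(ns) - 500
  l10 <- mean(vapply(1:4, function(s) lag1cor(dAll[1, s, , ], 10),
                     numeric(1)))
  expect_lt(abs(l10), 0.05)
})

test_that("near-zero noise amplitude leaves the series unchanged", {
  clean <- cleanSeries(getPhantom())
  n <- applyNoise(clean, noiseSpec(baseSigma = 1e-9, seed = 1))
  expect_lt(max(abs(seriesData(n) - seriesData(clean))), 1e-6)
})

test_that("phantom spec validation rejects bad inputs", {
  expect_error(phantomSpec(gridShape = c(12, 8, 64)), "in-plane")
  expect_error(phantomSpec(enhancementCurve = c(0, 1, 1), nTimepoints = 3L),
               "maximum")
  expect_error(phantomSpec(vesselContrast = -1), "levels")
  expect_error(noiseSpec(baseSigma = 0), "baseSigma")
  expect_error(noiseSpec(gainCoef = -1.5), "positive")
  # degenerate all-zero curve is explicitly allowed
  expect_s4_class(phantomSpec(enhancementCurve = rep(0, 3), nTimepoints = 3L),
                  "PhantomSpec")
})
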