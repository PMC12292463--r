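test_that("pixel-shuffle downsampling matches an explicit index oracle", {
  # stride 1 is the identity
  x <- matrix(runif(36), 6)
  expect_equal(pdDownsample(x, 1)[, ], x, ignore_attr = TRUE)
  expect_error(pdDownsample(x, 0), "stride")

  # brute-force index oracle: sub-image (a,b) holds pixels = (a,b) mod s
  oracle <- function(img, s) {
    h <- nrow(img) / s; w <- ncol(img) / s
    out <- matrix(0, nrow(img), ncol(img))
    for (a in 1:s) for (b in 1:s)
      for (i in 1:h) for (j in 1:w)
        out[(a - 1) * h + i, (b - 1) * w + j] <-
          img[(i - 1) * s + a, (j - 1) * s + b]
    out
  }
  ramp <- matrix(1:16, 4, 4)
  expect_equal(pdDownsample(ramp, 2)[, ], oracle(ramp, 2),
               ignore_attr = TRUE)
  x6 <- matrix(rnorm(36), 6)
  expect_equal(pdDownsample(x6, 3)[, ], oracle(x6, 3), ignore_attr = TRUE)
})

test_that("pd_inverse is the exact inverse for all strides and shapes", {
  set.seed(2)
  for (s in c(1L, 2L, 3L, 5L)) {
    x <- matrix(rnorm(100), 10)
    expect_identical(pdInverse(pdDownsample(x, s), s), x)
    # non-divisible shapes round-trip through recorded reflect padding
    y <- matrix(rnorm(11 * 7), 11, 7)
    expect_identical(pdInverse(pdDownsample(y, s), s), y)
  }
})

test_that("the receptive field structurally excludes the center pixel", {
  m <- new("DenoiserModel", params = perfusionBSN:::bsnInit(tinyBSN(), seed = 2),
           bsnConfig = tinyBSN(), pdConfig = pdConfig(),
           fingerprint = list(), lossHistory = numeric())
  set.seed(3)
  img <- matrix(rnorm(24 * 24), 24)
  out <- bsnForward(m, img)
  expect_identical(dim(out), dim(img))
  # huge perturbation at one pixel leaves that output pixel untouched
  for (pt in list(c(12, 13), c(5, 20), c(18, 7))) {
    img2 <- img
    img2[pt[1], pt[2]] <- img2[pt[1], pt[2]] + 1e6
    out2 <- bsnForward(m, img2)
    expect_identical(out[pt[1], pt[2]], out2[pt[1], pt[2]])
    expect_gt(max(abs(out2 - out)), 0)  # but it does reach neighbors
  }
  expect_error(bsnForward(m, matrix(c(NA, 1:3), 2)), "finite")
})

test_that("numerical receptive-field map is zero at center, nonzero in a ring", {
  params <- perfusionBSN:::bsnInit(tinyBSN(), seed = 4)
  set.seed(4)
  img <- matrix(rnorm(20 * 20), 20)
  i <- 10; j <- 10
  eps <- 1e-5
  grad <- function(di, dj) {
    a <- img; a[i + di, j + dj] <- a[i + di, j + dj] + eps
    b <- img; b[i + di, j + dj] <- b[i + di, j + dj] - eps
    (perfusionBSN:::bsnNetForward(params, a)[i, j] -
     perfusionBSN:::bsnNetForward(params, b)[i, j]) / (2 * eps)
  }
  expect_identical(grad(0, 0), 0)
  ring <- c(grad(0, 1), grad(1, 0), grad(-1, -1), grad(2, 0), grad(0, -2))
  expect_gt(max(abs(ring)), 1e-8)
})

test_that("constant input yields a spatially constant interior response", {
  params <- perfusionBSN:::bsnInit(tinyBSN(), seed = 5)
  out <- perfusionBSN:::bsnNetForward(params, matrix(1, 30, 30))
  interior <- out[10:20, 10:20]
  expect_lt(max(interior) - min(interior), 1e-10)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tinyBSN()
  params <- perfusionBSN:::bsnInit(cfg, seed = 6)
  set.seed(6)
  img <- matrix(rnorm(144), 12)
  tgt <- matrix(rnorm(144), 12)
  fw <- perfusionBSN:::bsnNetForward(params, img, training = TRUE)
  dout <- 2 * (fw$out - tgt) / length(tgt)
  g <- perfusionBSN:::bsnNetBackward(params, fw$cache, dout)
  lossAt <- function(p) mean((perfusionBSN:::bsnNetForward(p, img) - tgt)^2)
  eps <- 1e-6
  checkEntries <- function(getW, setW, gW, n = 3) {
    W <- getW(params)
    for (idx in sample(length(W), n)) {
      pp <- params; Wp <- W; Wp[idx] <- Wp[idx] + eps
      pm <- params; Wm <- W; Wm[idx] <- Wm[idx] - eps
      num <- (lossAt(setW(pp, Wp)) - lossAt(setW(pm, Wm))) / (2 * eps)
      expect_equal(gW[idx], num, tolerance = 1e-4)
    }
  }
  checkEntries(function(p) p$head$W,
               function(p, W) { p$head$W <- W; p }, g$head$dW)
  checkEntries(function(p) p$branches[[1]]$masked$W,
               function(p, W) { p$branches[[1]]$masked$W <- W; p },
               g$branches[[1]]$masked$dW)
  checkEntries(function(p) p$branches[[2]]$blocks[[1]]$dconv$W,
               function(p, W) { p$branches[[2]]$blocks[[1]]$dconv$W <- W; p },
               g$branches[[2]]$blocks[[1]]$dconv$dW)
  checkEntries(function(p) p$tail[[2]]$W,
               function(p, W) { p$tail[[2]]$W <- W; p }, g$tail[[2]]$dW)
})

test_that("training is deterministic, loss decreases, zero LR is a no-op", {
  b <- getPhantom()
  ps <- peakSlices(b, 3:6)
  cfgT <- trainConfig(epochs = 12L, patchSize = 20L, batchSize = 2L,
                      seed = 9L)
  pdc <- pdConfig(strideTrain = 5L, strideTest = 2L)
  m1 <- trainSelfSupervised(ps$noisy, cfgT, tinyBSN(), pdc)
  m2 <- trainSelfSupervised(ps$noisy, cfgT, tinyBSN(), pdc)
  expect_identical(m1@params, m2@params)
  lh <- lossHistory(m1)
  expect_identical(length(lh), 12L)
  # averaged early-vs-late trend
  expect_gt(mean(lh[1:4]), mean(lh[9:12]))

  m0 <- trainSelfSupervised(ps$noisy,
                            trainConfig(epochs = 2L, patchSize = 20L,
                                        learningRate = 0, seed = 9L),
                            tinyBSN(), pdc)
  init <- perfusionBSN:::bsnInit(tinyBSN(), seed = 9L)
  expect_equal(m0@params, init, tolerance = 1e-12)

  expect_error(
    trainSelfSupervised(ps$noisy, trainConfig(patchSize = 21L), tinyBSN(),
                        pdc),
    "divisible")
})

test_that("refinement-free inference returns the base PD estimate", {
  b <- getPhantom()
  ps <- peakSlices(b, 5)
  y <- ps$noisy[[1]]
  m <- trainSelfSupervised(list(y), trainConfig(epochs = 1L, patchSize = 20L,
                                                seed = 2L),
                           tinyBSN(), pdConfig(refineT = 0L))
  out <- denoiseAPBSN(m, y, seed = 1)
  s <- perfusionBSN:::robustScale(y)
  base <- perfusionBSN:::apbsnPass(m@params, y / s, 2L) * s
  expect_equal(out, base)
  expect_identical(dim(out), dim(y))
  expect_true(all(is.finite(out)))
  # refinement is deterministic given the seed
  m2 <- trainSelfSupervised(list(y), trainConfig(epochs = 1L, patchSize = 20L,
                                                 seed = 2L),
                            tinyBSN(), pdConfig(refineT = 4L))
  expect_identical(denoiseAPBSN(m2, y, seed = 7),
                   denoiseAPBSN(m2, y, seed = 7))
})

test_that("configuration validity catches structural violations", {
  expect_error(bsnConfig(branchKernels = c(4L, 5L)), "odd")
  expect_error(bsnConfig(channels = 4L), "channels")
  expect_error(pdConfig(strideTrain = 2L, strideTest = 2L), "exceed")
  expect_error(pdConfig(refineFraction = 1), "refineFraction")
})
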