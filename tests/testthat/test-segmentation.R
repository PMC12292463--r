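makeTrimodal <- function(n = 48, seed = 4, modes = c(10, 50, 100), sd = 1) {
  set.seed(seed)
  cls <- matrix(sample(0:2, n * n, replace = TRUE), n)
  img <- matrix(stats::rnorm(n * n, mean = modes[cls + 1], sd = sd), n)
  list(img = img, cls = cls)
}

test_that("k-means recovers well-separated intensity classes", {
  tm <- makeTrimodal()
  mask <- matrix(TRUE, 48, 48)
  seg <- kmeansSegment(tm$img, mask, k = 3L, seed = 1L)
  acc <- mean(segLabels(seg) == tm$cls)
  expect_gte(acc, 0.99)
  expect_true(all(diff(clusterMeans(seg)) > 0))
})

test_that("k-means labeling conventions and degenerate input", {
  tm <- makeTrimodal(n = 24)
  mask <- matrix(FALSE, 24, 24); mask[5:20, 5:20] <- TRUE
  seg <- kmeansSegment(tm$img, mask, k = 3L, seed = 2L)
  expect_true(all(segLabels(seg)[!mask] == -1L))
  expect_true(all(segLabels(seg)[mask] %in% 0:2))
  seg1 <- kmeansSegment(tm$img, mask, k = 1L, seed = 2L)
  expect_true(all(segLabels(seg1)[mask] == 0L))
  expect_error(kmeansSegment(matrix(5, 10, 10), matrix(TRUE, 10, 10)),
               "degenerate")
})

test_that("labels depend only on intensity, not pixel order", {
  tm <- makeTrimodal(n = 32)
  mask <- matrix(TRUE, 32, 32)
  seg <- kmeansSegment(tm$img, mask, k = 3L, seed = 5L)
  segT <- kmeansSegment(t(tm$img), t(mask), k = 3L, seed = 5L)
  expect_identical(segLabels(segT), t(segLabels(seg)))
})

test_that("affine intensity rescaling leaves the label map unchanged", {
  tm <- makeTrimodal(n = 32, seed = 7)
  mask <- matrix(TRUE, 32, 32)
  seg <- kmeansSegment(tm$img, mask, k = 3L, seed = 3L)
  seg2 <- kmeansSegment(3.5 * tm$img + 20, mask, k = 3L, seed = 3L)
  expect_identical(segLabels(seg2), segLabels(seg))
  expect_equal(clusterMeans(seg2), 3.5 * clusterMeans(seg) + 20,
               tolerance = 1e-8)
})

test_that("gaussian baseline matches the closed-form kernel", {
  img <- matrix(runif(100), 10)
  expect_identical(gaussianBaseline(img, 0), img)
  expect_equal(gaussianBaseline(matrix(4.2, 20, 20), 1.5),
               matrix(4.2, 20, 20), tolerance = 1e-12)
  expect_error(gaussianBaseline(img, -1), "sigma")
  # impulse response equals the normalized Gaussian kernel (radius 3 sigma)
  sigma <- 1.2
  n <- 31
  imp <- matrix(0, n, n); imp[16, 16] <- 1
  out <- gaussianBaseline(imp, sigma)
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  expected <- matrix(0, n, n)
  expected[(16 - r):(16 + r), (16 - r):(16 + r)] <- outer(k, k)
  expect_equal(out, expected, tolerance = 1e-6)
})

test_that("gaussian tuning finds sensible optima", {
  expect_identical(as.numeric(tuneGaussian(list(matrix(1:16, 4)),
                                           list(matrix(1:16, 4)),
                                           sigmas = 0)), 0)
  set.seed(6)
  clean <- list(matrix(rep(c(0, 10), each = 200), 20))
  expect_identical(as.numeric(tuneGaussian(clean, clean,
                                           sigmas = seq(0, 2, 0.5))), 0)
  expect_error(tuneGaussian(clean, clean, sigmas = numeric()), "empty")
  # white-noise phantom: optimum strictly inside the grid. (Under the
  # default spatially correlated noise the optimum collapses to ~0 --
  # small-kernel averaging cannot suppress correlated noise, which is the
  # very failure mode blind-spot PD denoising addresses.)
  b <- simulatePhantom(phantomSpec(),
                       noiseSpec(correlationFwhm = 0, seed = 6L), seed = 6L)
  ps <- peakSlices(b, 5:7)
  grid <- seq(0, 3, by = 0.25)
  best <- as.numeric(tuneGaussian(ps$noisy, ps$clean, grid))
  expect_gt(best, 0)
  expect_lt(best, 3)
})

test_that("metrics agree with their defining formulas", {
  set.seed(7)
  a <- matrix(runif(400, 0, 10), 20)
  b <- matrix(runif(400, 0, 10), 20)
  # PSNR against a direct MSE computation
  mse <- mean((a - b)^2)
  expect_equal(psnr(a, b), 10 * log10(max(b)^2 / mse), tolerance = 1e-9)
  m <- imageMetrics(b, b)
  expect_identical(m$psnr, 120)
  expect_equal(m$ssim, 1)
  # region SNR = mean(signal) / sd(background)
  img <- matrix(0, 10, 10)
  sig <- matrix(FALSE, 10, 10); sig[1:5, ] <- TRUE
  bgm <- !sig
  img[sig] <- 10
  img[bgm] <- rep(c(2, -2), 25)  # sample sd known
  m2 <- imageMetrics(img, img, signalMask = sig, backgroundMask = bgm)
  expect_equal(m2$snr, 10 / stats::sd(img[bgm]), tolerance = 1e-12)
  expect_equal(m2$snr, 10 / (2 * sqrt(50 / 49)), tolerance = 1e-12)
  flat <- matrix(5, 10, 10)
  expect_error(imageMetrics(flat, flat, signalMask = sig,
                            backgroundMask = bgm),
               "zero-variance")
  expect_true(is.finite(m2$sharpness))
})
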