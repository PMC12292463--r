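# Objective image-quality metrics: PSNR, SSIM, region SNR, gradient
# sharpness. These are the software counterparts of reader-scored SNR,
# sharpness and overall quality.

# Mean structural similarity (standard Gaussian-window SSIM).
ssimIndex <- function(x, y, sigma = 1.5, L = max(y) - min(y)) {
  if (L <= 0) L <- 1
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mx <- smoothGaussian2D(x, sigma)
  my <- smoothGaussian2D(y, sigma)
  sxx <- smoothGaussian2D(x * x, sigma) - mx^2
  syy <- smoothGaussian2D(y * y, sigma) - my^2
  sxy <- smoothGaussian2D(x * y, sigma) - mx * my
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

# Central-difference gradient magnitude.
gradientMagnitude <- function(x) {
  gx <- x * 0; gy <- x * 0
  n <- nrow(x); m <- ncol(x)
  gx[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / 2
  gy[, 2:(m - 1)] <- (x[, 3:m] - x[, 1:(m - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

# Boundary pixels of a binary mask (mask minus its 4-neighborhood erosion).
maskEdges <- function(mask) {
  m <- mask > 0
  er <- m
  n <- nrow(m); c <- ncol(m)
  er[2:(n - 1), 2:(c - 1)] <- m[2:(n - 1), 2:(c - 1)] &
    m[1:(n - 2), 2:(c - 1)] & m[3:n, 2:(c - 1)] &
    m[2:(n - 1), 1:(c - 2)] & m[2:(n - 1), 3:c]
  er[c(1, n), ] <- FALSE; er[, c(1, c)] <- FALSE
  m & !er
}

#' Objective image-quality metrics
#'
#' PSNR and SSIM of \code{test} against \code{reference}; optionally a
#' region-based SNR (mean of the signal region divided by the standard
#' deviation of the background region) and an edge sharpness (mean
#' gradient magnitude of \code{test} over the boundary pixels of the
#' signal mask).
#'
#' @param test,reference 2D matrices of identical shape.
#' @param signalMask optional binary matrix marking the signal region.
#' @param backgroundMask optional binary matrix marking a background
#'   (noise-only) region; must have nonzero intensity variance.
#' @return one-row data.frame with columns psnr, ssim, snr, sharpness
#'   (the latter two NA when masks are absent).
#' @export
imageMetrics <- function(test, reference, signalMask = NULL,
                         backgroundMask = NULL) {
  stopifnot(all(dim(test) == dim(reference)))
  out <- data.frame(psnr = psnr(test, reference),
                    ssim = ssimIndex(test, reference),
                    snr = NA_real_, sharpness = NA_real_)
  if (!is.null(backgroundMask) && !is.null(signalMask)) {
    bg <- test[backgroundMask > 0]
    if (stats::sd(bg) == 0) stop("zero-variance background region")
    out$snr <- mean(test[signalMask > 0]) / stats::sd(bg)
  }
  if (!is.null(signalMask)) {
    e <- maskEdges(signalMask)
    if (any(e)) out$sharpness <- mean(gradientMagnitude(test)[e])
  }
  out
}
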