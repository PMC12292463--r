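# Pixel-wise fractal-dimension mapping of perfusion images by differential
# box counting (DBC) on the intensity surface. A flat surface has FD 2.0;
# maximally rough surfaces approach 3.

# Start indices of the full r-sized blocks covering n pixels (centered
# grid; partial edge blocks are dropped -- mixing block areas bends the
# log-log fit, since N(r) then no longer scales with (n/r)^2).
blockStarts <- function(n, r) {
  nb <- n %/% r
  off <- (n - nb * r) %/% 2L
  off + seq(1L, nb * r, by = r)
}

# Raw DBC slope for one patch (no clipping). Returns c(fd, r2).
dbcSlope <- function(patch, scales) {
  P <- min(dim(patch))
  g <- patch - min(patch)
  G <- max(g)
  if (!is.finite(G)) stop("non-finite patch")
  if (G <= 0) return(c(2, 1))  # flat surface: FD baseline exactly 2
  logN <- numeric(length(scales))
  for (i in seq_along(scales)) {
    r <- scales[i]
    h <- r * G / P  # box height: intensity range scaled to the box size
    rs <- blockStarts(nrow(g), r); cs <- blockStarts(ncol(g), r)
    tot <- 0
    for (a in rs) {
      ae <- a + r - 1L
      for (b in cs) {
        be <- b + r - 1L
        blk <- g[a:ae, b:be]
        # continuous box count with unit floor: integer (ceil/floor) box
        # tallies quantize the count and demonstrably compress the
        # log-log slope; a flat column still occupies one box
        tot <- tot + max((max(blk) - min(blk)) / h, 1)
      }
    }
    logN[i] <- log(tot)
  }
  x <- log(1 / scales)
  mx <- mean(x); my <- mean(logN)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (logN - my)) / sxx
  ssr <- sum((my + slope * (x - mx) - logN)^2)
  sst <- sum((logN - my)^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  c(slope, r2)
}

#' Local fractal dimension of a patch
#'
#' Differential box counting: for each box size r the patch is covered by
#' a centered grid of full r x r pixel columns (partial edge blocks are
#' dropped); the number of boxes of height
#' \code{h = r * range / P} needed to cover the intensity surface in each
#' column is \code{max((max - min) / h, 1)} (a continuous count with unit
#' floor; intensities are taken relative to the patch minimum, making the
#' estimate invariant to intensity scaling). The FD is the least-squares
#' slope of log(total box count) against log(1/r), clipped to the
#' [1.9, 3.1] guard band. A constant patch returns the flat-surface
#' baseline 2.0 exactly.
#'
#' @param patch 2D numeric matrix, at least as large as the biggest scale.
#' @param scales integer box sizes (>= 3 of them).
#' @return scalar FD, with attribute \code{r2} (fit quality).
#' @export
fdLocal <- function(patch, scales = c(2, 3, 4, 5, 7)) {
  if (length(scales) < 3L) stop("need at least 3 scales")
  if (min(dim(patch)) < max(scales))
    stop("patch smaller than the biggest scale")
  sr <- dbcSlope(patch, scales)
  fd <- min(max(sr[1], 1.9), 3.1)
  attr(fd, "r2") <- sr[2]
  fd
}

#' Pixel-wise fractal-dimension map
#'
#' Slides an odd window over the image and evaluates \code{\link{fdLocal}}
#' at every interior pixel; border pixels take the nearest valid value.
#' The per-pixel R^2 of the log-log fit is recorded alongside.
#'
#' @param image 2D numeric matrix larger than the window.
#' @param window odd window size >= 5 (default 11).
#' @param scales box sizes, all <= window.
#' @return an \linkS4class{FDMap}.
#' @export
fdMap <- function(image, window = 11L, scales = c(2, 3, 4, 5, 7)) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 5L) stop("window must be odd and >= 5")
  if (any(dim(image) <= window)) stop("window larger than image")
  if (max(scales) > window) stop("scales must not exceed the window")
  h <- window %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  vals <- matrix(NA_real_, nr, nc)
  qual <- matrix(NA_real_, nr, nc)
  for (i in (h + 1L):(nr - h)) {
    rows <- (i - h):(i + h)
    for (j in (h + 1L):(nc - h)) {
      sr <- dbcSlope(image[rows, (j - h):(j + h)], scales)
      vals[i, j] <- min(max(sr[1], 1.9), 3.1)
      qual[i, j] <- sr[2]
    }
  }
  # borders: nearest valid value
  ri <- pmin(pmax(seq_len(nr), h + 1L), nr - h)
  ci <- pmin(pmax(seq_len(nc), h + 1L), nc - h)
  vals <- vals[ri, ci]
  qual <- qual[ri, ci]
  new("FDMap", values = vals, window = window, scales = as.numeric(scales),
      fitQuality = qual)
}

#' Fractional Brownian surface (estimator-validation oracle)
#'
#' Spectral synthesis of an approximately fractional Brownian surface with
#' Hurst exponent H: complex Gaussian spectral coefficients with amplitude
#' \eqn{f^{-(H+1)}} (power spectral density \eqn{f^{-(2H+2)}}), inverse
#' FFT, real part. The theoretical fractal dimension of such a surface is
#' 3 - H. Synthesis runs on an \code{over}-times finer grid and decimates,
#' which restores part of the beyond-Nyquist roughness a plain
#' grid-limited synthesis misses.
#'
#' @param n side length.
#' @param H Hurst exponent in (0, 1).
#' @param seed RNG seed.
#' @param over oversampling factor (default 2).
#' @return an n x n matrix, normalized to zero mean and unit sd.
#' @export
fbmSurface <- function(n, H, seed = 1L, over = 2L) {
  stopifnot(H > 0, H < 1, over >= 1L)
  N <- as.integer(n * over)
  f1 <- c(0:(floor(N / 2)), -((ceiling(N / 2) - 1):1)) / N
  fr <- matrix(f1, N, N); fc <- t(fr)
  f <- sqrt(fr^2 + fc^2)
  amp <- ifelse(f > 0, f^(-(H + 1)), 0)
  withSeed(seed, {
    phase <- matrix(complex(real = stats::rnorm(N * N),
                            imaginary = stats::rnorm(N * N)), N, N)
  })
  surf <- Re(stats::fft(amp * phase, inverse = TRUE)) / N^2
  surf <- surf[seq(1L, N, by = over), seq(1L, N, by = over)]
  (surf - mean(surf)) / stats::sd(surf)
}

#' Overlay a fractal-dimension map on a MIP image
#'
#' Renders the grayscale MIP with the FD values color-mapped (blue = 2,
#' red = 3) inside the mask; outside the mask the plain grayscale shows
#' through. Deterministic: fixed inputs and color map give byte-identical
#' PNG output.
#'
#' @param mip 2D matrix (grayscale background).
#' @param fd an \linkS4class{FDMap} with matching shape.
#' @param mask 2D binary matrix.
#' @param file optional path of a PNG to write.
#' @param alpha blending weight of the color layer, in [0, 1].
#' @return (invisibly) the H x W x 3 RGB array.
#' @export
fdOverlay <- function(mip, fd, mask, file = NULL, alpha = 0.6) {
  vals <- fdValues(fd)
  if (!all(dim(mip) == dim(vals)) || !all(dim(mip) == dim(mask)))
    stop("shape mismatch between mip, fd and mask")
  g <- mip - min(mip)
  if (max(g) > 0) g <- g / max(g)
  t01 <- pmin(pmax((vals - 2), 0), 1)  # map [2,3] -> [0,1]
  rgb <- array(rep(g, 3), c(dim(mip), 3))
  m <- mask > 0
  if (any(m)) {
    # simple blue->red ramp
    colR <- t01; colG <- 1 - abs(2 * t01 - 1); colB <- 1 - t01
    rgb[, , 1][m] <- (1 - alpha) * g[m] + alpha * colR[m]
    rgb[, , 2][m] <- (1 - alpha) * g[m] + alpha * colG[m]
    rgb[, , 3][m] <- (1 - alpha) * g[m] + alpha * colB[m]
  }
  if (!is.null(file)) png::writePNG(rgb, file)
  invisible(rgb)
}
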