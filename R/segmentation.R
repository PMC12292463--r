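# K-means intensity segmentation of the lung region and the Gaussian
# baseline denoiser.

# k-means++ seeding (Arthur & Vassilvitskii) on a numeric vector.
kppInit <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1L)]
  if (k > 1L) for (j in 2:k) {
    d2 <- Reduce(pmin, lapply(centers[1:(j - 1)], function(c0) (x - c0)^2))
    if (sum(d2) <= 0) centers[j] <- x[sample.int(length(x), 1L)]
    else centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
  }
  centers
}

#' K-means segmentation of masked intensities
#'
#' Clusters the masked pixel intensities into k classes with k-means
#' (k-means++ initialization, 10 seeded restarts keeping the lowest
#' inertia); labels are relabeled so cluster means ascend (0 = low,
#' k-1 = high), with -1 outside the mask. The default k = 3 gives the
#' low-/medium-/high-intensity partition of the lung region.
#'
#' @param image 2D numeric matrix.
#' @param mask 2D binary matrix; must contain at least k distinct values.
#' @param k number of classes (default 3).
#' @param seed RNG seed.
#' @param restarts k-means++ restarts (default 10).
#' @return a \linkS4class{SegmentationMap}.
#' @export
kmeansSegment <- function(image, mask, k = 3L, seed = 1L, restarts = 10L) {
  stopifnot(all(dim(image) == dim(mask)))
  m <- mask > 0
  x <- image[m]
  if (length(unique(x)) < k) stop("degenerate clustering input")
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      init <- kppInit(x, k)
      km <- tryCatch(
        stats::kmeans(x, centers = matrix(unique(init), ncol = 1),
                      iter.max = 100L, algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(km) || length(km$size) < k) {
        km <- suppressWarnings(
          stats::kmeans(x, centers = k, iter.max = 100L, nstart = 1L))
      }
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  ord <- order(best$centers[, 1])
  relabel <- integer(k); relabel[ord] <- seq_len(k) - 1L
  labels <- matrix(-1L, nrow(image), ncol(image))
  labels[m] <- relabel[best$cluster]
  new("SegmentationMap", labels = labels,
      clusterMeans = as.numeric(best$centers[ord, 1]))
}

#' Gaussian baseline denoiser
#'
#' Convolution with a normalized Gaussian kernel (reflect borders); the
#' conventional comparison baseline. sigma = 0 returns the input unchanged.
#'
#' @param image 2D numeric matrix.
#' @param sigma kernel standard deviation in pixels; >= 0.
#' @return filtered matrix.
#' @export
gaussianBaseline <- function(image, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  smoothGaussian2D(image, sigma)
}

#' Tune the Gaussian baseline on matched pairs
#'
#' Sweeps a sigma grid and returns the value maximizing mean PSNR against
#' the clean references (phantom-only: requires ground truth).
#'
#' @param noisy list of noisy 2D matrices.
#' @param clean matched list of clean references.
#' @param sigmas numeric grid of candidate sigmas.
#' @return the best sigma, with attribute \code{psnr} (the swept means).
#' @export
tuneGaussian <- function(noisy, clean, sigmas = seq(0, 3, by = 0.25)) {
  if (!length(sigmas)) stop("empty sigma grid")
  stopifnot(length(noisy) == length(clean), length(noisy) >= 1L)
  means <- vapply(sigmas, function(s) {
    mean(mapply(function(yv, cv) psnr(gaussianBaseline(yv, s), cv),
                noisy, clean))
  }, numeric(1))
  best <- sigmas[which.max(means)]
  attr(best, "psnr") <- means
  best
}
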