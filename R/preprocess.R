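# Preprocessing of dynamic series: background subtraction, peak-phase
# selection, maximum intensity projection, lung-mask estimation.

#' Background-subtract a dynamic series
#'
#' Subtracts the mean of the baseline (pre-contrast) frames from every
#' frame; negatives are clipped to 0 so the magnitude-image convention and
#' downstream non-negativity are preserved. With clipping the operation is
#' idempotent for a fixed baseline set.
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param baselineFrames integer indices of pre-contrast frames, or
#'   \code{"auto"}: all frames before the first whose whole-volume mean
#'   exceeds 10\% of the series' maximal frame mean (falling back to frame 1).
#' @return the subtracted \linkS4class{DynamicSeries}, with
#'   \code{baselineIndex} set to the last baseline frame.
#' @export
backgroundSubtract <- function(series, baselineFrames = "auto") {
  stopifnot(is(series, "DynamicSeries"))
  d <- dim(series@data)
  frameMeans <- apply(series@data, 1, mean)
  if (identical(baselineFrames, "auto")) {
    lo <- min(frameMeans); hi <- max(frameMeans)
    thresh <- lo + 0.1 * (hi - lo)
    first <- which(frameMeans > thresh)[1]
    baselineFrames <- if (is.na(first) || first <= 1L) 1L else seq_len(first - 1L)
  }
  baselineFrames <- as.integer(baselineFrames)
  if (!length(baselineFrames)) stop("empty baseline frame set")
  if (any(baselineFrames < 1L | baselineFrames > d[1]))
    stop("baseline frame index out of range")
  if (which.max(frameMeans) %in% baselineFrames)
    warning("baseline set contains the peak frame")
  base <- apply(series@data[baselineFrames, , , , drop = FALSE], c(2, 3, 4), mean)
  out <- series@data
  for (t in seq_len(d[1])) out[t, , , ] <- pmax(out[t, , , ] - base, 0)
  dynamicSeries(out, voxelSpacing = series@voxelSpacing,
                baselineIndex = max(baselineFrames))
}

#' Select the peak-perfusion frame
#'
#' Returns the timepoint with the largest mean intensity within the mask,
#' on a background-subtracted series. Ties break to the earliest index.
#'
#' @param series background-subtracted \linkS4class{DynamicSeries}.
#' @param mask binary 3D (slice, row, col) volume; must be nonempty.
#' @return integer frame index.
#' @export
selectPeakFrame <- function(series, mask) {
  stopifnot(is(series, "DynamicSeries"))
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  m <- apply(series@data, 1, function(v) mean(v[mask]))
  if (all(m <= 0)) stop("no enhancement detected")
  which.max(m)  # which.max takes the earliest maximum
}

#' Maximum intensity projection
#'
#' Element-wise maximum across a slab of slices of a (slice, row, col)
#' volume.
#'
#' @param volume 3D array (slice, row, col).
#' @param slab integer slice indices; defaults to all slices.
#' @return 2D (row, col) matrix.
#' @export
computeMIP <- function(volume, slab = seq_len(dim(volume)[1])) {
  stopifnot(length(dim(volume)) == 3L)
  slab <- as.integer(slab)
  if (!length(slab)) stop("empty slab")
  if (any(slab < 1L | slab > dim(volume)[1])) stop("slab out of bounds")
  apply(volume[slab, , , drop = FALSE], c(2, 3), max)
}

# Default MIP slab: up to `n` slices centered on the mask centroid.
mipSlab <- function(mask, n = 20L) {
  sl <- which(apply(mask > 0, 1, any))
  if (!length(sl)) sl <- seq_len(dim(mask)[1])
  ctr <- round(mean(sl))
  half <- n %/% 2L
  lo <- max(1L, ctr - half); hi <- min(dim(mask)[1], lo + n - 1L)
  seq(max(1L, hi - n + 1L), hi)
}

# 3D connected components (6-connectivity) via igraph on the mask voxels.
connectedComponents3D <- function(mask) {
  d <- dim(mask)
  idx <- which(mask > 0)
  if (!length(idx)) return(list(labels = array(0L, d), sizes = integer()))
  pos <- arrayInd(idx, d)
  lin <- function(p) p[, 1] + (p[, 2] - 1L) * d[1] + (p[, 3] - 1L) * d[1] * d[2]
  id <- integer(prod(d)); id[idx] <- seq_along(idx)
  edges <- list()
  for (ax in 1:3) {
    q <- pos; q[, ax] <- q[, ax] + 1L
    ok <- q[, ax] <= d[ax]
    nb <- lin(q[ok, , drop = FALSE])
    present <- id[nb] > 0L
    if (any(present))
      edges[[length(edges) + 1L]] <-
        cbind(which(ok)[present], id[nb[present]])
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), 0, 2)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(em)) g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)
  labels <- array(0L, d)
  labels[idx] <- comp$membership
  list(labels = labels, sizes = as.integer(comp$csize))
}

#' Estimate a lung mask from an enhancement volume
#'
#' Otsu threshold on the (intensity-compressed) background-subtracted
#' peak-phase volume, morphological closing per slice, then selection of the
#' largest connected components (all components at least 20\% the size of
#' the largest, so both lungs survive). For phantoms, the generator's
#' ground-truth mask can be passed through downstream instead.
#'
#' @param volume background-subtracted 3D (slice, row, col) volume.
#' @return binary 3D array.
#' @export
estimateLungMask <- function(volume) {
  stopifnot(length(dim(volume)) == 3L)
  if (all(volume <= 0)) stop("empty mask: volume has no enhancement")
  # log compresses the bright vessel tail so Otsu separates
  # enhancing lung from background rather than vessels from the rest
  v <- log1p(pmax(volume, 0))
  v <- v / max(v)
  th <- EBImage::otsu(EBImage::Image(matrix(v, nrow = dim(volume)[2])))
  mask <- array(v > th, dim(volume))
  brush <- EBImage::makeBrush(5, "disc")
  for (s in seq_len(dim(mask)[1]))
    mask[s, , ] <- EBImage::closing(mask[s, , ] * 1, brush) > 0
  cc <- connectedComponents3D(mask)
  if (!length(cc$sizes)) stop("empty mask after processing")
  keep <- which(cc$sizes >= 0.2 * max(cc$sizes))
  out <- array(cc$labels %in% keep, dim(volume))
  if (!any(out)) stop("empty mask after processing")
  out
}
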