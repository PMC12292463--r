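# Synthetic lung-perfusion phantom: thorax geometry, bifurcating vascular
# trees, bolus-like enhancement, and spatially correlated noise with a
# smooth gain field. Stands in for clinical data in all tests.

# Ellipsoid descriptors of the two lung compartments for a grid.
lungGeometry <- function(gridShape) {
  S <- gridShape[1]; R <- gridShape[2]; C <- gridShape[3]
  list(
    list(center = c(S / 2 + 0.5, R * 0.48, C * 0.31),
         radii  = c(S * 0.42, R * 0.33, C * 0.16)),
    list(center = c(S / 2 + 0.5, R * 0.48, C * 0.69),
         radii  = c(S * 0.42, R * 0.33, C * 0.16)))
}

ellipsoidMask <- function(gridShape, center, radii) {
  S <- gridShape[1]; R <- gridShape[2]; C <- gridShape[3]
  ds <- ((seq_len(S) - center[1]) / radii[1])^2
  dr <- ((seq_len(R) - center[2]) / radii[2])^2
  dc <- ((seq_len(C) - center[3]) / radii[3])^2
  outer(outer(ds, dr, `+`), dc, `+`) <= 1
}

# Rotate unit vector v by angle theta about unit axis a (Rodrigues).
rotateAbout <- function(v, a, theta) {
  v * cos(theta) + pracmaCross(a, v) * sin(theta) + a * sum(a * v) * (1 - cos(theta))
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unitPerp <- function(v) {
  # a unit vector perpendicular to v (deterministic choice)
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- pracmaCross(v, w)
  p / sqrt(sum(p^2))
}

# Mark voxels within `rad` of segment p0-p1 into levelVol (0 = empty),
# assigning `lev` only where still empty. Returns updated levelVol.
rasterizeTube <- function(levelVol, p0, p1, rad, lev) {
  d <- dim(levelVol)
  lo <- pmax(floor(pmin(p0, p1) - rad - 1), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + rad + 1), d)
  if (any(lo > hi)) return(levelVol)
  gs <- seq(lo[1], hi[1]); gr <- seq(lo[2], hi[2]); gc <- seq(lo[3], hi[3])
  pts <- as.matrix(expand.grid(s = gs, r = gr, c = gc))
  v <- p1 - p0
  vv <- sum(v^2)
  w <- sweep(pts, 2, p0)
  tproj <- if (vv > 0) pmin(1, pmax(0, (w %*% v) / vv)) else matrix(0, nrow(pts))
  closest <- sweep(tproj %*% rbind(v), 2, p0, `+`)
  dist2 <- rowSums((pts - closest)^2)
  hit <- dist2 <= (rad + 0.5)^2
  if (any(hit)) {
    idx <- pts[hit, , drop = FALSE]
    lin <- idx[, 1] + (idx[, 2] - 1) * d[1] + (idx[, 3] - 1) * d[1] * d[2]
    empty <- levelVol[lin] == 0L
    levelVol[lin[empty]] <- lev
  }
  levelVol
}

#' Generate the phantom's vascular tree
#'
#' Grows one recursive bifurcating tube tree per lung compartment. Branch
#' length, radius and direction are refined per level with seeded angular
#' jitter; branch radius decreases geometrically with level, giving the
#' multiscale structure that fractal analysis needs. Subdivision stops (with
#' a warning) when branch radii would fall below half a voxel.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @return binary 3D (slice, row, col) array with attribute
#'   \code{levelCounts}, the voxel tally of each branching level.
#' @export
generateVesselTree <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  g <- spec@gridShape
  levelVol <- array(0L, g)
  nLev <- spec@vesselLevels
  radius0 <- max(1.6, 0.04 * g[3])
  subVoxelWarned <- FALSE

  grow <- function(p0, dir, len, rad, lev) {
    p1 <- p0 + dir * len
    levelVol <<- rasterizeTube(levelVol, p0, p1, rad, lev)
    if (lev >= nLev) return(invisible())
    childRad <- rad * 0.7
    if (childRad < 0.5) {
      if (!subVoxelWarned) {
        warning("vessel subdivision stopped: sub-voxel branch radius")
        subVoxelWarned <<- TRUE
      }
      return(invisible())
    }
    for (sgn in c(-1, 1)) {
      ang <- (25 + stats::runif(1, -8, 8)) * pi / 180
      axis <- rotateAbout(unitPerp(dir), dir, stats::runif(1, 0, 2 * pi))
      d2 <- rotateAbout(dir, axis, sgn * ang)
      # pulmonary trees in a coronal slab run predominantly in-plane:
      # damp the through-slice component so slices see curvilinear
      # vessels, not isolated through-plane dots
      d2[1] <- 0.25 * d2[1]
      d2 <- d2 / sqrt(sum(d2^2))
      grow(p1, d2, len * 0.75, childRad, lev + 1L)
    }
    invisible()
  }

  withSeed(seed, {
    for (lung in lungGeometry(g)) {
      start <- c(lung$center[1], lung$center[2] - 0.8 * lung$radii[2],
                 lung$center[3])
      grow(start, c(0, 1, 0), 0.55 * lung$radii[2], radius0, 1L)
    }
  })
  counts <- tabulate(levelVol[levelVol > 0L], nbins = nLev)
  out <- array(levelVol > 0L, g)
  attr(out, "levelCounts") <- counts
  out
}

#' Generate the clean phantom series and ground-truth mask
#'
#' Builds static anatomy (body oval at \code{bodyLevel}, lung ellipsoids at
#' \code{parenchymaLevel}) and a per-voxel enhancement component (vessels at
#' \code{vesselContrast}, parenchyma at half its baseline level). Frame t of
#' the clean series is \code{static + enhancementCurve[t] * enhancement};
#' an optional spherical lesion scales enhancement by (1 - deficit).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed seed forwarded to \code{\link{generateVesselTree}}.
#' @return a \linkS4class{PhantomBundle} whose noisy slot still equals the
#'   clean series; apply \code{\link{applyNoise}} to complete it.
#' @export
generatePhantom <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  g <- spec@gridShape
  lungs <- lungGeometry(g)
  lungEll <- ellipsoidMask(g, lungs[[1]]$center, lungs[[1]]$radii) |
             ellipsoidMask(g, lungs[[2]]$center, lungs[[2]]$radii)
  body <- ellipsoidMask(g, c(g[1] / 2 + 0.5, g[2] * 0.5, g[3] * 0.5),
                        c(g[1], g[2] * 0.46, g[3] * 0.44))
  vessels <- generateVesselTree(spec, seed)
  static <- array(0, g)
  static[body] <- spec@bodyLevel
  static[lungEll] <- spec@parenchymaLevel
  static[vessels] <- spec@parenchymaLevel

  enh <- array(0, g)
  enh[lungEll] <- 0.5 * spec@parenchymaLevel
  enh[vessels] <- spec@vesselContrast
  if (length(spec@lesion)) {
    l <- spec@lesion
    les <- ellipsoidMask(g, l$center, rep(l$radius, 3))
    enh[les] <- enh[les] * (1 - l$deficit)
  }

  dat <- array(0, c(spec@nTimepoints, g))
  for (t in seq_len(spec@nTimepoints)) {
    dat[t, , , ] <- static + spec@enhancementCurve[t] * enh
  }
  mask <- array(lungEll | vessels, g)
  clean <- dynamicSeries(dat)
  new("PhantomBundle", clean = clean, noisy = clean, lungMask = mask,
      enhancement = enh, spec = spec, noise = NULL)
}

# In-plane radial quadratic gain field for an RxC slice.
gainField <- function(R, C, coef) {
  cr <- (R + 1) / 2; cc <- (C + 1) / 2
  rn2 <- outer(((seq_len(R) - cr) / (R / 2))^2,
               ((seq_len(C) - cc) / (C / 2))^2, `+`) / 2
  1 + coef * rn2
}

#' Apply spatially correlated, spatially varying noise
#'
#' Adds zero-mean Gaussian noise, independently per timepoint: white noise
#' is smoothed in-plane with a Gaussian kernel of the requested FWHM,
#' rescaled to unit variance (by the kernel's theoretical
#' \eqn{\sqrt{\sum k^2}} factor), multiplied by the radial gain field and by
#' \code{baseSigma}, and added to the clean data. The local noise standard
#' deviation therefore equals \code{baseSigma * gain}. The stored series is
#' clipped at 0 to preserve the magnitude-image convention, which only
#' affects near-zero background voxels.
#'
#' @param clean a \linkS4class{DynamicSeries}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @return a noisy \linkS4class{DynamicSeries}; deterministic given the
#'   spec's seed.
#' @export
applyNoise <- function(clean, noise) {
  stopifnot(is(clean, "DynamicSeries"), is(noise, "NoiseSpec"))
  d <- dim(clean@data)
  sigmaPix <- noise@correlationFwhm / (2 * sqrt(2 * log(2)))
  k1 <- gaussianKernel1D(sigmaPix)
  unitSd <- sum(k1^2)  # sd of separable-smoothed unit white noise
  gain <- gainField(d[3], d[4], noise@gainCoef)
  out <- clean@data
  withSeed(noise@seed, {
    for (t in seq_len(d[1])) {
      for (s in seq_len(d[2])) {
        w <- matrix(stats::rnorm(d[3] * d[4]), d[3], d[4])
        if (sigmaPix > 0) w <- smoothGaussian2D(w, sigmaPix) / unitSd
        out[t, s, , ] <- out[t, s, , ] + noise@baseSigma * gain * w
      }
    }
  })
  out[out < 0] <- 0
  dynamicSeries(out, voxelSpacing = clean@voxelSpacing,
                baselineIndex = clean@baselineIndex)
}

#' Simulate a complete phantom bundle
#'
#' Convenience wrapper: \code{\link{generatePhantom}} followed by
#' \code{\link{applyNoise}}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @param seed seed for the vessel-tree geometry (noise uses the
#'   NoiseSpec's own seed).
#' @return a \linkS4class{PhantomBundle} with clean and noisy series.
#' @export
simulatePhantom <- function(spec = phantomSpec(), noise = noiseSpec(),
                            seed = 1L) {
  b <- generatePhantom(spec, seed)
  new("PhantomBundle", clean = b@clean, noisy = applyNoise(b@clean, noise),
      lungMask = b@lungMask, enhancement = b@enhancement, spec = spec,
      noise = noise)
}
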