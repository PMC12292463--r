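#' @import methods
NULL

#' DynamicSeries: a 4D dynamic perfusion acquisition
#'
#' Container for a dynamic contrast-enhanced series stored as a 4D array
#' ordered (time, slice, row, col); slices are coronal planes. All values
#' must be finite and non-negative (magnitude images).
#'
#' @slot data 4D numeric array (time, slice, row, col).
#' @slot voxelSpacing numeric length-3 voxel spacing in mm (slice, row, col).
#' @slot baselineIndex integer index of the last pre-contrast frame, or NA.
#' @export
setClass("DynamicSeries",
  representation(data = "array", voxelSpacing = "numeric",
                 baselineIndex = "integer"),
  prototype(voxelSpacing = c(1, 1, 1), baselineIndex = NA_integer_),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4D (time, slice, row, col) array")
    if (d[1] < 1L) return("at least one timepoint required")
    if (!all(is.finite(object@data))) return("data must be finite")
    if (any(object@data < 0)) return("data must be non-negative")
    if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
      return("voxelSpacing must be 3 positive values")
    TRUE
  })

#' Construct a DynamicSeries
#'
#' @param data 4D array (time, slice, row, col) or 3D array (a single
#'   timepoint is added in front).
#' @param voxelSpacing voxel spacing in mm.
#' @param baselineIndex optional last pre-contrast frame index.
#' @return a \linkS4class{DynamicSeries}.
#' @export
dynamicSeries <- function(data, voxelSpacing = c(1, 1, 1),
                          baselineIndex = NA_integer_) {
  if (length(dim(data)) == 3L)
    data <- array(data, c(1L, dim(data)))
  new("DynamicSeries", data = data, voxelSpacing = as.numeric(voxelSpacing),
      baselineIndex = as.integer(baselineIndex))
}

#' PhantomSpec: geometry and contrast of a synthetic lung-perfusion phantom
#'
#' @slot gridShape integer (slices, rows, cols); in-plane dims must be >= 16.
#' @slot nTimepoints number of dynamic frames.
#' @slot vesselLevels branching depth of the synthetic vascular tree.
#' @slot vesselContrast peak vessel enhancement (arbitrary units).
#' @slot parenchymaLevel baseline lung parenchyma intensity.
#' @slot bodyLevel surrounding-tissue intensity.
#' @slot enhancementCurve per-timepoint scale factors in [0, 1], unique max.
#' @slot lesion empty list, or list(center=, radius=, deficit=) describing a
#'   spherical perfusion deficit (deficit in [0, 1]).
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", nTimepoints = "integer",
                 vesselLevels = "integer", vesselContrast = "numeric",
                 parenchymaLevel = "numeric", bodyLevel = "numeric",
                 enhancementCurve = "numeric", lesion = "list"),
  validity = function(object) {
    g <- object@gridShape
    if (length(g) != 3L) return("gridShape must be (slices, rows, cols)")
    if (g[1] < 4L) return("at least 4 slices required")
    if (any(g[2:3] < 16L)) return("in-plane grid dims must be >= 16")
    if (object@vesselLevels < 1L) return("vesselLevels must be >= 1")
    lv <- c(object@vesselContrast, object@parenchymaLevel, object@bodyLevel)
    if (any(lv < 0)) return("intensity levels must be >= 0")
    ec <- object@enhancementCurve
    if (length(ec) != object@nTimepoints)
      return("enhancementCurve length must equal nTimepoints")
    if (any(ec < 0 | ec > 1)) return("enhancementCurve must lie in [0, 1]")
    # an all-zero curve (no enhancement) is a valid degenerate phantom;
    # otherwise the peak must be unique
    if (any(ec > 0) && sum(ec == max(ec)) != 1L)
      return("enhancementCurve must attain its maximum at exactly one index")
    if (length(object@lesion)) {
      l <- object@lesion
      if (!all(c("center", "radius", "deficit") %in% names(l)))
        return("lesion needs center, radius, deficit")
      if (l$deficit < 0 || l$deficit > 1) return("lesion deficit must be in [0, 1]")
    }
    TRUE
  })

#' Construct a PhantomSpec
#'
#' Defaults describe a small coronal thorax: two ellipsoidal lungs of
#' low-intensity parenchyma inside a brighter body oval, a bifurcating
#' vascular tree per lung, and a 6-frame bolus-like enhancement curve with a
#' single peak.
#'
#' @param gridShape (slices, rows, cols), default c(12, 64, 64).
#' @param nTimepoints number of frames, default 6.
#' @param vesselLevels tree depth, default 4.
#' @param vesselContrast peak vessel enhancement, default 300.
#' @param parenchymaLevel lung baseline, default 60.
#' @param bodyLevel surrounding tissue, default 120.
#' @param enhancementCurve per-frame factors in [0,1] with one maximum.
#' @param lesion optional list(center=, radius=, deficit=).
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = c(12L, 64L, 64L), nTimepoints = 6L,
                        vesselLevels = 4L, vesselContrast = 300,
                        parenchymaLevel = 60, bodyLevel = 120,
                        enhancementCurve = c(0, 0.05, 0.4, 1, 0.7, 0.45),
                        lesion = list()) {
  if (length(enhancementCurve) != nTimepoints && nTimepoints == 6L)
    nTimepoints <- length(enhancementCurve)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      nTimepoints = as.integer(nTimepoints),
      vesselLevels = as.integer(vesselLevels),
      vesselContrast = vesselContrast, parenchymaLevel = parenchymaLevel,
      bodyLevel = bodyLevel, enhancementCurve = enhancementCurve,
      lesion = lesion)
}

#' NoiseSpec: spatially correlated, spatially varying noise model
#'
#' Additive zero-mean Gaussian noise, spatially correlated by Gaussian
#' smoothing (in-plane) and modulated by a smooth multiplicative gain field.
#' The smoothed field is rescaled to unit variance before gain
#' multiplication, so the local noise standard deviation is
#' `baseSigma * gain`.
#'
#' @slot baseSigma noise sd in image units; > 0.
#' @slot correlationFwhm FWHM (pixels) of the correlating kernel; 0 = white.
#' @slot gainCoef coefficient of the radial quadratic gain
#'   `1 + gainCoef * (r / rmax)^2` (higher noise at the periphery, as with
#'   surface-coil inhomogeneity); must keep the gain positive.
#' @slot seed integer RNG seed.
#' @export
setClass("NoiseSpec",
  representation(baseSigma = "numeric", correlationFwhm = "numeric",
                 gainCoef = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@baseSigma <= 0) return("baseSigma must be > 0")
    if (object@correlationFwhm < 0) return("correlationFwhm must be >= 0")
    if (1 + min(0, object@gainCoef) <= 0)
      return("gain field must be strictly positive everywhere")
    TRUE
  })

#' Construct a NoiseSpec
#' @param baseSigma noise sd, default 20.
#' @param correlationFwhm correlation FWHM in pixels, default 3.
#' @param gainCoef radial quadratic gain coefficient, default 0.5.
#' @param seed RNG seed.
#' @return a \linkS4class{NoiseSpec}.
#' @export
noiseSpec <- function(baseSigma = 20, correlationFwhm = 3, gainCoef = 0.5,
                      seed = 1L) {
  new("NoiseSpec", baseSigma = baseSigma, correlationFwhm = correlationFwhm,
      gainCoef = gainCoef, seed = as.integer(seed))
}

#' PhantomBundle: a phantom with ground truth
#'
#' @slot clean noise-free \linkS4class{DynamicSeries}.
#' @slot noisy the same series with noise applied (may equal clean before
#'   \code{\link{applyNoise}}).
#' @slot lungMask binary 3D (slice, row, col) lung mask.
#' @slot enhancement 3D per-voxel enhancement component at unit curve value.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @slot noise the \linkS4class{NoiseSpec} used, or NULL-like empty list slotless default.
#' @export
setClass("PhantomBundle",
  representation(clean = "DynamicSeries", noisy = "DynamicSeries",
                 lungMask = "array", enhancement = "array",
                 spec = "PhantomSpec", noise = "ANY"),
  validity = function(object) {
    if (!identical(dim(object@clean@data), dim(object@noisy@data)))
      return("clean and noisy series must have identical shapes")
    if (!any(object@lungMask > 0)) return("lungMask must be nonempty")
    if (!identical(dim(object@lungMask), dim(object@clean@data)[-1]))
      return("lungMask shape must match a single volume")
    TRUE
  })

#' BSNConfig: blind-spot network architecture
#'
#' Two parallel branches, each starting with a centrally masked convolution
#' (3x3 and 5x5) followed by dilated residual blocks (dilation 2 for the 3x3
#' branch, 3 for the 5x5 branch); branch outputs are concatenated and fused
#' by 1x1 convolutions. The masked first layer plus dilation choice make the
#' receptive field of every output pixel structurally exclude its own input
#' pixel.
#'
#' @slot branchKernels two odd masked-convolution sizes.
#' @slot dilations per-branch dilation rates.
#' @slot nDilatedBlocks dilated residual blocks per branch.
#' @slot channels feature width.
#' @slot nTailConvs number of 1x1 convolutions after concatenation
#'   (the last one maps to a single output channel, linearly).
#' @export
setClass("BSNConfig",
  representation(branchKernels = "integer", dilations = "integer",
                 nDilatedBlocks = "integer", channels = "integer",
                 nTailConvs = "integer"),
  validity = function(object) {
    if (length(object@branchKernels) != 2L || any(object@branchKernels %% 2L == 0L))
      return("branchKernels must be two odd sizes")
    if (length(object@dilations) != 2L || any(object@dilations < 1L))
      return("dilations must be two values >= 1")
    if (object@channels < 8L) return("channels must be >= 8")
    if (object@nDilatedBlocks < 1L) return("nDilatedBlocks must be >= 1")
    if (object@nTailConvs < 1L) return("nTailConvs must be >= 1")
    TRUE
  })

#' Construct a BSNConfig
#' @param branchKernels masked kernel sizes, default c(3, 5).
#' @param dilations per-branch dilations, default c(2, 3).
#' @param nDilatedBlocks residual blocks per branch, default 4.
#' @param channels feature width, default 32.
#' @param nTailConvs 1x1 fusion convolutions, default 3.
#' @return a \linkS4class{BSNConfig}.
#' @export
bsnConfig <- function(branchKernels = c(3L, 5L), dilations = c(2L, 3L),
                      nDilatedBlocks = 4L, channels = 32L, nTailConvs = 3L) {
  new("BSNConfig", branchKernels = as.integer(branchKernels),
      dilations = as.integer(dilations),
      nDilatedBlocks = as.integer(nDilatedBlocks),
      channels = as.integer(channels), nTailConvs = as.integer(nTailConvs))
}

#' PDConfig: asymmetric pixel-shuffle downsampling
#'
#' Training uses a large stride (default 5) to break spatial noise
#' correlation; inference uses a smaller stride (default 2) plus T random
#' replacement refinement passes whose outputs are averaged.
#'
#' @slot strideTrain training PD stride.
#' @slot strideTest inference PD stride; must be < strideTrain.
#' @slot refineT number of refinement passes (default 16).
#' @slot refineFraction fraction of pixels replaced per pass, in (0, 1).
#' @export
setClass("PDConfig",
  representation(strideTrain = "integer", strideTest = "integer",
                 refineT = "integer", refineFraction = "numeric"),
  validity = function(object) {
    if (object@strideTest < 1L) return("strideTest must be >= 1")
    if (object@strideTrain <= object@strideTest)
      return("strideTrain must exceed strideTest")
    if (object@refineT < 0L) return("refineT must be >= 0")
    if (object@refineFraction <= 0 || object@refineFraction >= 1)
      return("refineFraction must be in (0, 1)")
    TRUE
  })

#' Construct a PDConfig
#' @param strideTrain training stride, default 5.
#' @param strideTest inference stride, default 2.
#' @param refineT refinement passes, default 16.
#' @param refineFraction replaced fraction per pass, default 0.5.
#' @return a \linkS4class{PDConfig}.
#' @export
pdConfig <- function(strideTrain = 5L, strideTest = 2L, refineT = 16L,
                     refineFraction = 0.5) {
  new("PDConfig", strideTrain = as.integer(strideTrain),
      strideTest = as.integer(strideTest), refineT = as.integer(refineT),
      refineFraction = refineFraction)
}

#' TrainConfig: self-supervised training settings
#'
#' @slot epochs passes over the slice set.
#' @slot learningRate Adam step size.
#' @slot patchSize square patch side; must be divisible by the training
#'   stride.
#' @slot batchSize patches per optimizer step.
#' @slot optimizer "adam" (only supported value).
#' @slot seed RNG seed controlling init and sampling.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", learningRate = "numeric",
                 patchSize = "integer", batchSize = "integer",
                 optimizer = "character", seed = "integer"),
  validity = function(object) {
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@learningRate < 0) return("learningRate must be >= 0")
    if (object@patchSize < 10L) return("patchSize too small")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (!object@optimizer %in% "adam") return("optimizer must be 'adam'")
    TRUE
  })

#' Construct a TrainConfig
#' @param epochs default 20.
#' @param learningRate default 1e-3.
#' @param patchSize default 40 (divisible by the default training stride 5).
#' @param batchSize default 2.
#' @param optimizer "adam".
#' @param seed RNG seed, default 1.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(epochs = 20L, learningRate = 1e-3, patchSize = 40L,
                        batchSize = 2L, optimizer = "adam", seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs), learningRate = learningRate,
      patchSize = as.integer(patchSize), batchSize = as.integer(batchSize),
      optimizer = optimizer, seed = as.integer(seed))
}

#' PnPConfig: plug-and-play ADMM settings
#'
#' @slot rho fidelity/prior weighting parameter (> 0); the reference value
#'   balancing noise control against blurring is 1.
#' @slot nIters number of ADMM iterations K (1..100); default 3.
#' @slot seed inference seed (refinement randomness inside the denoiser).
#' @slot xUpdateRule "scaled": x = (y + rho*(z - u)) / (1 + rho), the exact
#'   minimizer of the x-subproblem in scaled form; "literal": the
#'   typographically literal x = (y + rho*z - u) / (1 + rho).
#' @slot zRule "standard": z = D(x + u) (scaled-ADMM z-step);
#'   "literal": z = D(x) + u.
#' @export
setClass("PnPConfig",
  representation(rho = "numeric", nIters = "integer", seed = "integer",
                 xUpdateRule = "character", zRule = "character"),
  validity = function(object) {
    if (object@rho <= 0) return("rho must be > 0")
    if (object@nIters < 1L || object@nIters > 100L)
      return("nIters must be in 1..100")
    if (!object@xUpdateRule %in% c("scaled", "literal"))
      return("xUpdateRule must be 'scaled' or 'literal'")
    if (!object@zRule %in% c("standard", "literal"))
      return("zRule must be 'standard' or 'literal'")
    TRUE
  })

#' Construct a PnPConfig
#' @param rho weighting parameter, default 1.
#' @param nIters ADMM iterations, default 3.
#' @param seed inference seed, default 0.
#' @param xUpdateRule "scaled" (default) or "literal".
#' @param zRule "standard" (default) or "literal".
#' @return a \linkS4class{PnPConfig}.
#' @export
pnpConfig <- function(rho = 1, nIters = 3L, seed = 0L,
                      xUpdateRule = "scaled", zRule = "standard") {
  new("PnPConfig", rho = rho, nIters = as.integer(nIters),
      seed = as.integer(seed), xUpdateRule = xUpdateRule, zRule = zRule)
}

#' DenoiserModel: trained blind-spot network + inference configuration
#'
#' @slot params nested list of convolution weights and biases.
#' @slot bsnConfig the \linkS4class{BSNConfig} used.
#' @slot pdConfig the \linkS4class{PDConfig} used.
#' @slot fingerprint list(seed, epochs, steps, dataHash) provenance record.
#' @slot lossHistory mean training loss per epoch.
#' @export
setClass("DenoiserModel",
  representation(params = "list", bsnConfig = "BSNConfig",
                 pdConfig = "PDConfig", fingerprint = "list",
                 lossHistory = "numeric"),
  validity = function(object) {
    if (!length(object@params)) return("model has no parameters")
    TRUE
  })

#' FDMap: pixel-wise fractal dimension map
#'
#' Values live on the intensity-surface scale: 2.0 for a flat surface,
#' approaching 3 for maximally rough surfaces. Stored values are clipped to
#' [1.9, 3.1] (a 0.1 fit-noise guard band around the theoretical range).
#'
#' @slot values matrix of fractal dimensions.
#' @slot window odd sliding-window size (>= 5).
#' @slot scales box sizes used in the log-log fit (>= 3 of them).
#' @slot fitQuality per-pixel R^2 of the log-log regression.
#' @export
setClass("FDMap",
  representation(values = "matrix", window = "integer", scales = "numeric",
                 fitQuality = "matrix"),
  validity = function(object) {
    eps <- 0.1
    if (any(object@values < 2 - eps - 1e-9 | object@values > 3 + eps + 1e-9))
      return("FD values outside [1.9, 3.1]")
    if (object@window %% 2L == 0L || object@window < 5L)
      return("window must be odd and >= 5")
    if (length(object@scales) < 3L) return("need >= 3 scales")
    if (!identical(dim(object@values), dim(object@fitQuality)))
      return("fitQuality shape must match values")
    TRUE
  })

#' SegmentationMap: k-means intensity labels
#'
#' @slot labels integer matrix; 0..k-1 in ascending intensity order inside
#'   the mask, -1 outside.
#' @slot clusterMeans intensity centroids in ascending order.
#' @export
setClass("SegmentationMap",
  representation(labels = "matrix", clusterMeans = "numeric"),
  validity = function(object) {
    k <- length(object@clusterMeans)
    if (k > 1L && any(diff(object@clusterMeans) <= 0))
      return("clusterMeans must be strictly ascending")
    inside <- object@labels[object@labels >= 0L]
    if (length(inside) && max(inside) >= k)
      return("labels exceed number of clusters")
    TRUE
  })
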