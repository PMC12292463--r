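#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))
#' @rdname accessors
#' @export
setGeneric("cleanSeries", function(object) standardGeneric("cleanSeries"))
#' @rdname accessors
#' @export
setGeneric("noisySeries", function(object) standardGeneric("noisySeries"))
#' @rdname accessors
#' @export
setGeneric("lungMask", function(object) standardGeneric("lungMask"))
#' @rdname accessors
#' @export
setGeneric("enhancementMap", function(object) standardGeneric("enhancementMap"))
#' @rdname accessors
#' @export
setGeneric("fdValues", function(object) standardGeneric("fdValues"))
#' @rdname accessors
#' @export
setGeneric("fitQuality", function(object) standardGeneric("fitQuality"))
#' @rdname accessors
#' @export
setGeneric("segLabels", function(object) standardGeneric("segLabels"))
#' @rdname accessors
#' @export
setGeneric("clusterMeans", function(object) standardGeneric("clusterMeans"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname accessors
#' @export
setMethod("seriesData", "DynamicSeries", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "DynamicSeries", function(object) object@voxelSpacing)
#' @rdname accessors
#' @export
setMethod("nTimepoints", "DynamicSeries", function(object) dim(object@data)[1])
#' @rdname accessors
#' @export
setMethod("cleanSeries", "PhantomBundle", function(object) object@clean)
#' @rdname accessors
#' @export
setMethod("noisySeries", "PhantomBundle", function(object) object@noisy)
#' @rdname accessors
#' @export
setMethod("lungMask", "PhantomBundle", function(object) object@lungMask)
#' @rdname accessors
#' @export
setMethod("enhancementMap", "PhantomBundle", function(object) object@enhancement)
#' @rdname accessors
#' @export
setMethod("fdValues", "FDMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("fitQuality", "FDMap", function(object) object@fitQuality)
#' @rdname accessors
#' @export
setMethod("segLabels", "SegmentationMap", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("clusterMeans", "SegmentationMap", function(object) object@clusterMeans)
#' @rdname accessors
#' @export
setMethod("lossHistory", "DenoiserModel", function(object) object@lossHistory)

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicSeries: %d timepoints, %d slices of %dx%d\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm; baseline frame: %s\n",
              paste(signif(object@voxelSpacing, 3), collapse = "x"),
              ifelse(is.na(object@baselineIndex), "unset",
                     object@baselineIndex)))
})

setMethod("show", "PhantomBundle", function(object) {
  d <- dim(object@clean@data)
  cat(sprintf("PhantomBundle: %d x %d x %d x %d (t,s,r,c); lung voxels: %d\n",
              d[1], d[2], d[3], d[4], sum(object@lungMask > 0)))
})

setMethod("show", "DenoiserModel", function(object) {
  cfg <- object@bsnConfig
  cat(sprintf(paste0("DenoiserModel (blind-spot network): %d channels, ",
                     "%d dilated blocks/branch, kernels %s, dilations %s\n"),
              cfg@channels, cfg@nDilatedBlocks,
              paste(cfg@branchKernels, collapse = "/"),
              paste(cfg@dilations, collapse = "/")))
  cat(sprintf("  PD stride train/test: %d/%d, refinement T=%d\n",
              object@pdConfig@strideTrain, object@pdConfig@strideTest,
              object@pdConfig@refineT))
  if (length(object@lossHistory))
    cat(sprintf("  trained %d epochs; final loss %.5f\n",
                length(object@lossHistory),
                utils::tail(object@lossHistory, 1)))
})

setMethod("show", "FDMap", function(object) {
  cat(sprintf("FDMap: %dx%d, window %d, scales {%s}; FD range [%.3f, %.3f]\n",
              nrow(object@values), ncol(object@values), object@window,
              paste(object@scales, collapse = ","),
              min(object@values), max(object@values)))
})

setMethod("show", "SegmentationMap", function(object) {
  cat(sprintf("SegmentationMap: %dx%d, %d classes; means %s\n",
              nrow(object@labels), ncol(object@labels),
              length(object@clusterMeans),
              paste(signif(object@clusterMeans, 4), collapse = ", ")))
})
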