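# End-to-end pipeline wiring and NIfTI I/O. Every stage output lands on
# disk so any stage can be re-run in isolation; a JSON manifest records
# versions, seeds, hashes and wall times.

#' Read a dynamic series from NIfTI
#'
#' Accepts 3D (single-phase) or 4D NIfTI; on disk volumes are stored
#' (row, col, slice[, time]) and are rearranged to the package's
#' (time, slice, row, col) convention.
#'
#' @param path NIfTI file path.
#' @return a \linkS4class{DynamicSeries}.
#' @export
readSeries <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  pd <- RNifti::pixdim(img)
  if (length(dim(a)) == 3L) a <- array(a, c(dim(a), 1L))
  if (length(dim(a)) != 4L) stop("expected 3D or 4D NIfTI")
  dat <- aperm(a, c(4, 3, 1, 2))  # (time, slice, row, col)
  sp <- c(if (length(pd) >= 3) pd[3] else 1, pd[1], pd[2])
  dynamicSeries(pmax(dat, 0), voxelSpacing = sp)
}

#' Write a volume or series as NIfTI
#'
#' 2D matrices, 3D (slice, row, col) volumes, 4D (time, slice, row, col)
#' series and \linkS4class{DynamicSeries} objects are supported; data are
#' stored as float32.
#'
#' @param volume the object to write.
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel spacing (slice, row, col) in mm.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path, spacing = c(1, 1, 1)) {
  if (is(volume, "DynamicSeries")) {
    spacing <- volume@voxelSpacing
    volume <- volume@data
  }
  nd <- length(dim(volume))
  a <- switch(as.character(nd),
    "2" = volume,
    "3" = aperm(volume, c(2, 3, 1)),
    "4" = aperm(volume, c(3, 4, 2, 1)),
    stop("unsupported dimensionality"))
  img <- RNifti::asNifti(a)
  pd <- c(spacing[2], spacing[3], spacing[1], 1)[seq_len(max(nd, 3))]
  RNifti::pixdim(img) <- pd[seq_len(nd)]
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Returns the full configuration list for \code{\link{runPipeline}} with
#' the given overrides applied (one level deep).
#'
#' @param ... named overrides.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    outDir = tempfile("run"),
    seed = 1L,
    stages = c("simulate", "preprocess", "denoise", "mip", "fd", "kmeans",
               "metrics"),
    input = NULL,                      # NIfTI path; NULL -> simulate
    phantom = phantomSpec(),
    noise = noiseSpec(),
    bsn = bsnConfig(),
    pd = pdConfig(),
    train = trainConfig(),
    pnp = pnpConfig(),
    model = NULL,                      # DenoiserModel; NULL -> train stage
    denoiseMethod = "pnp",             # "pnp", "apbsn" or "gaussian"
    gaussianSigma = 1,
    fdWindow = 11L,
    fdScales = c(2, 3, 4, 5, 7),
    kmeansK = 3L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of overrides for \code{\link{pipelineConfig}}. Scalar
#' fields map directly; the nested blocks \code{phantom}, \code{noise},
#' \code{bsn}, \code{pd}, \code{train} and \code{pnp} are passed as
#' argument lists to the corresponding constructors.
#'
#' @param path YAML file path.
#' @return configuration list for \code{\link{runPipeline}}.
#' @export
pipelineConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  ctors <- list(phantom = phantomSpec, noise = noiseSpec, bsn = bsnConfig,
                pd = pdConfig, train = trainConfig, pnp = pnpConfig)
  for (nm in intersect(names(ctors), names(y)))
    y[[nm]] <- do.call(ctors[[nm]], y[[nm]])
  do.call(pipelineConfig, y)
}

#' Run the processing pipeline
#'
#' Executes the enabled stages in order: simulate (or read) the series,
#' background-subtract, select the peak frame, denoise every peak-phase
#' slice, project (MIP), map fractal dimension, segment by k-means, and
#' compute metrics. Each intermediate is written as NIfTI (plus CSV for
#' metrics) under \code{cfg$outDir}, and a JSON manifest records the
#' package version, seeds, per-stage wall times and MD5 hashes of every
#' output.
#'
#' @param cfg configuration list from \code{\link{pipelineConfig}}.
#' @return the manifest, invisibly (also written to manifest.json).
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "perfusionBSN",
                   version = as.character(utils::packageVersion("perfusionBSN")),
                   seed = cfg$seed, stages = cfg$stages,
                   timings = list(), outputs = list())
  state <- new.env(parent = emptyenv())
  out <- function(name) file.path(cfg$outDir, name)
  record <- function(name, path) {
    manifest$outputs[[name]] <<- list(file = basename(path),
                                      md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, body) {
    if (!name %in% cfg$stages) return(invisible())
    t0 <- proc.time()["elapsed"]
    body()
    manifest$timings[[name]] <<- round(proc.time()["elapsed"] - t0, 3)
  }

  stage("simulate", function() {
    bundle <- simulatePhantom(cfg$phantom, cfg$noise, seed = cfg$seed)
    state$bundle <- bundle
    state$series <- noisySeries(bundle)
    state$mask <- lungMask(bundle)
    writeVolume(state$series, out("noisy.nii.gz"))
    record("noisy", out("noisy.nii.gz"))
  })
  needsInput <- any(c("preprocess", "train", "denoise", "mip") %in% cfg$stages)
  if (needsInput && is.null(state$series)) {
    if (is.null(cfg$input))
      stop("no input: enable the simulate stage or set cfg$input")
    state$series <- readSeries(cfg$input)
  }

  stage("preprocess", function() {
    sub <- backgroundSubtract(state$series, "auto")
    if (is.null(state$mask))
      state$mask <- estimateLungMask(apply(sub@data, c(2, 3, 4), max))
    state$peak <- selectPeakFrame(sub, state$mask)
    state$sub <- sub
    state$peakVol <- sub@data[state$peak, , , ]
    writeVolume(sub, out("subtracted.nii.gz"))
    record("subtracted", out("subtracted.nii.gz"))
  })

  stage("train", function() {
    slices <- lapply(seq_len(dim(state$peakVol)[1]),
                     function(s) state$peakVol[s, , ])
    state$model <- trainSelfSupervised(slices, cfg$train, cfg$bsn, cfg$pd)
  })
  if (is.null(state$model)) state$model <- cfg$model

  stage("denoise", function() {
    v <- state$peakVol
    den <- array(0, dim(v))
    for (s in seq_len(dim(v)[1])) {
      y <- v[s, , ]
      den[s, , ] <- switch(cfg$denoiseMethod,
        gaussian = gaussianBaseline(y, cfg$gaussianSigma),
        apbsn = denoiseAPBSN(state$model, y, seed = cfg$seed + s),
        pnp = {
          pc <- cfg$pnp; pc@seed <- as.integer(cfg$seed + 101L * s)
          pnpDenoise(y, state$model, pc)
        },
        stop("unknown denoise method"))
    }
    state$denoised <- den
    writeVolume(den, out("denoised.nii.gz"))
    record("denoised", out("denoised.nii.gz"))
  })

  stage("mip", function() {
    vol <- if (!is.null(state$denoised)) state$denoised else state$peakVol
    slab <- mipSlab(state$mask)
    state$mip <- computeMIP(vol, slab)
    state$mipMask <- apply(state$mask[slab, , , drop = FALSE] > 0,
                           c(2, 3), any)
    writeVolume(state$mip, out("mip.nii.gz"))
    record("mip", out("mip.nii.gz"))
  })

  stage("fd", function() {
    fd <- fdMap(state$mip, cfg$fdWindow, cfg$fdScales)
    state$fd <- fd
    writeVolume(fdValues(fd), out("fd.nii.gz"))
    record("fd", out("fd.nii.gz"))
    fdOverlay(state$mip, fd, state$mipMask, file = out("fd_overlay.png"))
    record("fd_overlay", out("fd_overlay.png"))
  })

  stage("kmeans", function() {
    seg <- kmeansSegment(state$mip, state$mipMask, k = cfg$kmeansK,
                         seed = cfg$seed)
    state$seg <- seg
    writeVolume(segLabels(seg) * 1.0, out("kmeans.nii.gz"))
    record("kmeans", out("kmeans.nii.gz"))
  })

  stage("metrics", function() {
    if (is.null(state$bundle)) return(invisible())
    peak <- state$peak
    cleanSub <- backgroundSubtract(cleanSeries(state$bundle), "auto")
    rows <- list()
    for (s in seq_len(dim(state$peakVol)[1])) {
      ref <- cleanSub@data[peak, s, , ]
      m2 <- state$mask[s, , ] > 0
      if (!any(m2)) next
      for (meth in c("noisy", cfg$denoiseMethod)) {
        img <- if (meth == "noisy") state$peakVol[s, , ] else
          state$denoised[s, , ]
        mt <- imageMetrics(img, ref, signalMask = m2)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(slice = s, method = meth), mt)
      }
    }
    metrics <- do.call(rbind, rows)
    utils::write.csv(metrics, out("metrics.csv"), row.names = FALSE)
    record("metrics", out("metrics.csv"))
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
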