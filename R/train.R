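# Self-supervised training of the blind-spot network and asymmetric-PD
# inference with random-replacement refinement.

# ---- parameter-tree utilities -------------------------------------------

isLayer <- function(p) is.list(p) && !is.null(p$W)

gradsAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (!is.null(b$dW)) return(list(dW = a$dW + b$dW, db = a$db + b$db))
  out <- b
  for (i in seq_along(b)) out[[i]] <- gradsAdd(a[[i]], b[[i]])
  out
}

gradsScale <- function(g, s) {
  if (!is.null(g$dW)) return(list(dW = g$dW * s, db = g$db * s))
  for (i in seq_along(g)) g[[i]] <- gradsScale(g[[i]], s)
  g
}

adamInitState <- function(params) {
  if (isLayer(params))
    return(list(mW = params$W * 0, vW = params$W * 0,
                mb = params$b * 0, vb = params$b * 0))
  lapply(params, adamInitState)
}

adamStep <- function(params, grads, state, lr, t, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  if (isLayer(params)) {
    state$mW <- beta1 * state$mW + (1 - beta1) * grads$dW
    state$vW <- beta2 * state$vW + (1 - beta2) * grads$dW^2
    state$mb <- beta1 * state$mb + (1 - beta1) * grads$db
    state$vb <- beta2 * state$vb + (1 - beta2) * grads$db^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    params$W <- params$W - lr * (state$mW / c1) / (sqrt(state$vW / c2) + eps)
    params$b <- params$b - lr * (state$mb / c1) / (sqrt(state$vb / c2) + eps)
    if (length(params$maskRows)) params$W[params$maskRows, ] <- 0
    return(list(params = params, state = state))
  }
  keys <- if (!is.null(names(params))) names(params) else seq_along(params)
  for (nm in keys) {
    if (is.null(grads[[nm]])) next
    res <- adamStep(params[[nm]], grads[[nm]], state[[nm]], lr, t,
                    beta1, beta2, eps)
    params[[nm]] <- res$params
    state[[nm]] <- res$state
  }
  list(params = params, state = state)
}

# ---- training ------------------------------------------------------------

#' Train the blind-spot network self-supervised
#'
#' Trains on single noisy slices, no clean targets: each step downsamples a
#' random patch with the large training PD stride, runs the blind-spot
#' network on the mosaic, and minimizes the pixel-wise L1 distance between
#' the network output and the mosaic itself. Because the receptive field
#' excludes the center pixel, the loss is non-degenerate and its minimizer
#' predicts each (PD-decorrelated) noisy pixel from its neighbors. Slices
#' are normalized by a robust 99.9th-percentile scale before patch
#' extraction.
#'
#' @param slices list of 2D noisy matrices (e.g. background-subtracted
#'   peak-phase slices).
#' @param cfg a \linkS4class{TrainConfig}.
#' @param bsn a \linkS4class{BSNConfig}.
#' @param pd a \linkS4class{PDConfig}.
#' @param verbose print per-epoch loss.
#' @param init optional \linkS4class{DenoiserModel} (or raw parameter list)
#'   to warm-start from instead of a fresh seeded initialization.
#' @return a trained \linkS4class{DenoiserModel}; deterministic given the
#'   config seed.
#' @export
trainSelfSupervised <- function(slices, cfg = trainConfig(),
                                bsn = bsnConfig(), pd = pdConfig(),
                                verbose = FALSE, init = NULL) {
  stopifnot(length(slices) >= 1L)
  if (cfg@patchSize %% pd@strideTrain != 0L)
    stop("patchSize must be divisible by strideTrain")
  norm <- lapply(slices, function(s) s / robustScale(s))
  small <- vapply(norm, function(s) any(dim(s) < cfg@patchSize), logical(1))
  if (any(small)) stop("slices smaller than patchSize")
  params <- if (is.null(init)) bsnInit(bsn, seed = cfg@seed)
            else if (is(init, "DenoiserModel")) init@params
            else init
  state <- adamInitState(params)
  nBatch <- ceiling(length(norm) / cfg@batchSize)
  lossHist <- numeric(cfg@epochs)
  stepCount <- 0L
  withSeed(cfg@seed + 1L, {
    for (ep in seq_len(cfg@epochs)) {
      epochLoss <- 0
      nPatches <- 0L
      for (bt in seq_len(nBatch)) {
        acc <- NULL
        bl <- 0
        nb <- min(cfg@batchSize, length(norm) - (bt - 1L) * cfg@batchSize)
        for (j in seq_len(nb)) {
          sl <- norm[[sample.int(length(norm), 1L)]]
          r0 <- sample.int(nrow(sl) - cfg@patchSize + 1L, 1L)
          c0 <- sample.int(ncol(sl) - cfg@patchSize + 1L, 1L)
          patch <- sl[r0:(r0 + cfg@patchSize - 1L),
                      c0:(c0 + cfg@patchSize - 1L)]
          mosaic <- pdDownsample(patch, pd@strideTrain)
          fw <- bsnNetForward(params, mosaic, training = TRUE)
          resid <- fw$out - mosaic
          loss <- mean(abs(resid))
          if (!is.finite(loss))
            stop(sprintf("divergent loss (NaN/Inf) at epoch %d", ep))
          dout <- sign(resid) / length(resid)
          g <- bsnNetBackward(params, fw$cache, dout)
          acc <- gradsAdd(acc, g)
          bl <- bl + loss
          nPatches <- nPatches + 1L
        }
        acc <- gradsScale(acc, 1 / nb)
        stepCount <- stepCount + 1L
        res <- adamStep(params, acc, state, cfg@learningRate, stepCount)
        params <- res$params
        state <- res$state
        epochLoss <- epochLoss + bl
      }
      lossHist[ep] <- epochLoss / nPatches
      if (verbose)
        message(sprintf("epoch %d/%d  L1 loss %.5f", ep, cfg@epochs,
                        lossHist[ep]))
    }
  })
  new("DenoiserModel", params = params, bsnConfig = bsn, pdConfig = pd,
      fingerprint = list(seed = cfg@seed, epochs = cfg@epochs,
                         steps = stepCount,
                         dataHash = contentFingerprint(unlist(lapply(norm, sum)))),
      lossHistory = lossHist)
}

# ---- inference -----------------------------------------------------------

# One PD -> BSN -> inverse-PD pass on a normalized image.
apbsnPass <- function(params, img, s) {
  mosaic <- pdDownsample(img, s)
  o <- bsnNetForward(params, mosaic, training = FALSE)
  pdInverse(o, s, outDim = dim(img))
}

#' Denoise one image with the asymmetric-PD blind-spot network
#'
#' Inference uses the small test stride (asymmetric to the larger training
#' stride), then applies T random-replacement refinement passes: each pass
#' replaces a random fraction of the base estimate's pixels with the
#' original noisy pixels, re-runs the PD - BSN - inverse-PD path, and the T
#' pass outputs are averaged. Intensities are normalized by a robust
#' 99.9th-percentile scale before the network and restored afterwards.
#'
#' @param model a trained \linkS4class{DenoiserModel}.
#' @param y 2D noisy matrix.
#' @param seed seed for the refinement replacement masks.
#' @return denoised matrix of the same shape; deterministic given the seed.
#' @export
denoiseAPBSN <- function(model, y, seed = 0L) {
  stopifnot(is(model, "DenoiserModel"))
  if (!all(is.finite(y))) stop("non-finite input")
  pd <- model@pdConfig
  s <- robustScale(y)
  yn <- y / s
  base <- apbsnPass(model@params, yn, pd@strideTest)
  if (pd@refineT == 0L) return(base * s)
  acc <- matrix(0, nrow(y), ncol(y))
  withSeed(seed, {
    for (t in seq_len(pd@refineT)) {
      repl <- stats::runif(length(yn)) < pd@refineFraction
      tmp <- base
      tmp[repl] <- yn[repl]
      acc <- acc + apbsnPass(model@params, tmp, pd@strideTest)
    }
  })
  (acc / pd@refineT) * s
}
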