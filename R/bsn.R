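# Blind-spot network: architecture assembly, forward pass, exact backward
# pass, and the pixel-shuffle downsampling (PD) rearrangements.

#' Pixel-shuffle downsample
#'
#' Bijectively rearranges an image into an s x s grid of sub-images;
#' sub-image (a, b) holds the pixels at positions congruent to (a, b)
#' modulo s. If the dimensions are not divisible by s the image is
#' reflect-padded up to the next multiple and the padding is recorded in
#' attributes (\code{pdPad}, \code{pdDim}, \code{pdStride}) so that
#' \code{\link{pdInverse}} restores the original exactly.
#'
#' @param image 2D numeric matrix.
#' @param s integer stride >= 1.
#' @return the mosaic matrix.
#' @export
pdDownsample <- function(image, s) {
  s <- as.integer(s)
  if (s < 1L) stop("stride must be >= 1")
  d0 <- dim(image)
  pr <- (s - d0[1] %% s) %% s
  pc <- (s - d0[2] %% s) %% s
  if (pr || pc) {
    rmap <- c(seq_len(d0[1]), seq(d0[1] - 1L, by = -1L, length.out = pr))
    cmap <- c(seq_len(d0[2]), seq(d0[2] - 1L, by = -1L, length.out = pc))
    image <- image[rmap, cmap, drop = FALSE]
  }
  d <- dim(image)
  ridx <- as.vector(vapply(seq_len(s), function(a) seq(a, d[1], by = s),
                           integer(d[1] %/% s)))
  cidx <- as.vector(vapply(seq_len(s), function(b) seq(b, d[2], by = s),
                           integer(d[2] %/% s)))
  out <- image[ridx, cidx, drop = FALSE]
  attr(out, "pdPad") <- c(pr, pc)
  attr(out, "pdDim") <- d0
  attr(out, "pdStride") <- s
  out
}

#' Invert pixel-shuffle downsampling
#'
#' Exact inverse of \code{\link{pdDownsample}}; any recorded reflect
#' padding is cropped away.
#'
#' @param mosaic matrix produced by \code{\link{pdDownsample}} (or any
#'   matrix whose dims are divisible by s).
#' @param s integer stride.
#' @param outDim optional original (rows, cols) to crop to, overriding the
#'   recorded attribute.
#' @return the reconstructed image.
#' @export
pdInverse <- function(mosaic, s, outDim = attr(mosaic, "pdDim")) {
  s <- as.integer(s)
  if (s < 1L) stop("stride must be >= 1")
  d <- dim(mosaic)
  if (any(d %% s != 0L)) stop("mosaic dims not divisible by stride")
  ridx <- as.vector(vapply(seq_len(s), function(a) seq(a, d[1], by = s),
                           integer(d[1] %/% s)))
  cidx <- as.vector(vapply(seq_len(s), function(b) seq(b, d[2], by = s),
                           integer(d[2] %/% s)))
  out <- matrix(0, d[1], d[2])
  out[ridx, cidx] <- mosaic
  if (!is.null(outDim)) out <- out[seq_len(outDim[1]), seq_len(outDim[2]), drop = FALSE]
  out
}

# Build the parameter list for a BSNConfig (seeded).
bsnInit <- function(cfg, seed = 1L) {
  stopifnot(is(cfg, "BSNConfig"))
  C <- cfg@channels
  withSeed(seed, {
    params <- list(head = convLayer(1L, 1L, C))
    params$branches <- lapply(1:2, function(b) {
      br <- list(masked = convLayer(cfg@branchKernels[b], C, C, dil = 1L,
                                    masked = TRUE))
      br$blocks <- lapply(seq_len(cfg@nDilatedBlocks), function(i)
        list(dconv = convLayer(3L, C, C, dil = cfg@dilations[b]),
             pconv = convLayer(1L, C, C)))
      br
    })
    tailIn <- 2L * C
    params$tail <- lapply(seq_len(cfg@nTailConvs), function(j) {
      cin <- if (j == 1L) tailIn else C
      cout <- if (j == cfg@nTailConvs) 1L else C
      convLayer(1L, cin, cout)
    })
    params
  })
}

# Forward pass on an (H, W) matrix; returns list(out, cache) when
# training = TRUE, else just the output matrix.
bsnNetForward <- function(params, x, training = FALSE) {
  H <- nrow(x); W <- ncol(x)
  xin <- array(x, c(H, W, 1L))
  cache <- list()
  h0 <- convForward(params$head, xin, cache = training)
  h <- reluF(h0)
  branchOuts <- vector("list", 2L)
  for (b in 1:2) {
    br <- params$branches[[b]]
    m0 <- convForward(br$masked, h, cache = training)
    cur <- reluF(m0)
    blockCaches <- vector("list", length(br$blocks))
    for (i in seq_along(br$blocks)) {
      bl <- br$blocks[[i]]
      t0 <- convForward(bl$dconv, cur, cache = training)
      t1 <- reluF(t0)
      t2 <- convForward(bl$pconv, t1, cache = training)
      if (training) blockCaches[[i]] <- list(t0 = t0, t1 = t1, t2 = t2,
                                             input = cur)
      cur <- cur + t2
    }
    if (training)
      cache[[paste0("branch", b)]] <- list(m0 = m0, blocks = blockCaches,
                                           out = cur)
    branchOuts[[b]] <- cur
  }
  C <- dim(branchOuts[[1]])[3]
  catd <- array(0, c(H, W, 2L * C))
  catd[, , seq_len(C)] <- branchOuts[[1]]
  catd[, , C + seq_len(C)] <- branchOuts[[2]]
  u <- catd
  tailCaches <- vector("list", length(params$tail))
  nT <- length(params$tail)
  for (j in seq_len(nT)) {
    u0 <- convForward(params$tail[[j]], u, cache = training)
    if (training) tailCaches[[j]] <- list(u0 = u0, input = u)
    u <- if (j < nT) reluF(u0) else u0
  }
  out <- matrix(u, H, W)
  if (!training) return(out)
  cache$h0 <- h0; cache$h <- h; cache$cat <- catd; cache$tails <- tailCaches
  list(out = out, cache = cache)
}

# Backward pass: gradients of a scalar loss w.r.t. all parameters, given
# d(loss)/d(output). Structure of the returned list mirrors `params`.
bsnNetBackward <- function(params, cache, dout) {
  H <- nrow(dout); W <- ncol(dout)
  grads <- list()
  nT <- length(params$tail)
  du <- array(dout, c(H, W, 1L))
  grads$tail <- vector("list", nT)
  for (j in seq(nT, 1L)) {
    tc <- cache$tails[[j]]
    if (j < nT) du <- du * (tc$u0 > 0)
    bw <- convBackward(params$tail[[j]], tc$u0, du)
    grads$tail[[j]] <- list(dW = bw$dW, db = bw$db)
    du <- bw$dx
  }
  C <- dim(du)[3] %/% 2L
  dBranch <- list(du[, , seq_len(C), drop = FALSE],
                  du[, , C + seq_len(C), drop = FALSE])
  dh <- 0
  grads$branches <- vector("list", 2L)
  for (b in 1:2) {
    br <- params$branches[[b]]
    bc <- cache[[paste0("branch", b)]]
    dcur <- dBranch[[b]]
    gblocks <- vector("list", length(br$blocks))
    for (i in seq(length(br$blocks), 1L)) {
      bl <- br$blocks[[i]]; blc <- bc$blocks[[i]]
      # residual: out = input + pconv(relu(dconv(input)))
      bwP <- convBackward(bl$pconv, blc$t2, dcur)
      dt0 <- bwP$dx * (blc$t0 > 0)
      bwD <- convBackward(bl$dconv, blc$t0, dt0)
      gblocks[[i]] <- list(dconv = list(dW = bwD$dW, db = bwD$db),
                           pconv = list(dW = bwP$dW, db = bwP$db))
      dcur <- dcur + bwD$dx
    }
    dm0 <- dcur * (bc$m0 > 0)
    bwM <- convBackward(br$masked, bc$m0, dm0)
    grads$branches[[b]] <- list(masked = list(dW = bwM$dW, db = bwM$db),
                                blocks = gblocks)
    dh <- dh + bwM$dx
  }
  dh0 <- dh * (cache$h0 > 0)
  bwH <- convBackward(params$head, cache$h0, dh0)
  grads$head <- list(dW = bwH$dW, db = bwH$db)
  grads
}

#' Blind-spot network forward pass
#'
#' Applies the network to a 2D image (no PD, no normalization). The
#' receptive field of every output pixel structurally excludes the input
#' pixel at the same position: the only spatial layers are the centrally
#' masked first convolutions of each branch and dilated convolutions whose
#' offsets are multiples of the dilation, which can never sum back to zero
#' given the masked-kernel half-widths.
#'
#' @param model a \linkS4class{DenoiserModel}.
#' @param image 2D numeric matrix, all finite.
#' @return matrix of the same shape.
#' @export
bsnForward <- function(model, image) {
  stopifnot(is(model, "DenoiserModel"))
  if (!all(is.finite(image))) stop("non-finite input")
  bsnNetForward(model@params, image, training = FALSE)
}
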