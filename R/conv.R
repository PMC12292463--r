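# Minimal CNN layer kernels used by the blind-spot network: zero-padded
# dilated 2D convolutions via im2col + BLAS matrix products, with exact
# analytic gradients. Zero padding (not reflect) is essential: a mirror
# copy of a pixel would re-enter the receptive field of its own output
# position near borders and break the blind-spot guarantee. Feature maps
# are (H, W, C) double arrays; a layer's weights are a (k*k*Cin) x Cout
# matrix with tap-major, channel-minor row order. `maskRows` lists weight
# rows structurally pinned to zero (the center tap of a masked
# convolution).

convLayer <- function(k, cin, cout, dil = 1L, masked = FALSE, gain = 2) {
  # He-style init on the unmasked fan-in
  fanin <- k * k * cin - if (masked) cin else 0L
  W <- matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(gain / fanin)),
              k * k * cin, cout)
  maskRows <- integer()
  if (masked) {
    tc <- ((k + 1L) %/% 2L - 1L) * k + (k + 1L) %/% 2L
    maskRows <- (tc - 1L) * cin + seq_len(cin)
    W[maskRows, ] <- 0
  }
  list(W = W, b = numeric(cout), k = as.integer(k), dil = as.integer(dil),
       cin = as.integer(cin), cout = as.integer(cout), maskRows = maskRows)
}

# Zero-pad an (H, W, C) array by p on both spatial axes.
padZero3 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

im2col <- function(xp, H, W, k, dil, cin) {
  M <- matrix(0, H * W, k * k * cin)
  t <- 0L
  for (a in seq_len(k)) {
    rows <- seq.int((a - 1L) * dil + 1L, length.out = H)
    for (b in seq_len(k)) {
      t <- t + 1L
      cols <- seq.int((b - 1L) * dil + 1L, length.out = W)
      M[, ((t - 1L) * cin + 1L):(t * cin)] <-
        xp[rows, cols, , drop = FALSE]
    }
  }
  M
}

convForward <- function(ly, x, cache = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]
  p <- ly$dil * (ly$k - 1L) %/% 2L
  M <- if (ly$k == 1L) matrix(x, H * W, ly$cin)
       else im2col(padZero3(x, p), H, W, ly$k, ly$dil, ly$cin)
  Wm <- ly$W
  if (length(ly$maskRows)) Wm[ly$maskRows, ] <- 0
  y <- M %*% Wm
  y <- y + rep(ly$b, each = H * W)
  out <- array(y, c(H, W, ly$cout))
  if (cache) attr(out, "cache") <- list(M = M, H = H, W = W)
  out
}

convBackward <- function(ly, cacheOut, dy) {
  cc <- attr(cacheOut, "cache")
  H <- cc$H; W <- cc$W
  dyM <- matrix(dy, H * W, ly$cout)
  Wm <- ly$W
  if (length(ly$maskRows)) Wm[ly$maskRows, ] <- 0
  db <- colSums(dyM)
  dW <- crossprod(cc$M, dyM)
  if (length(ly$maskRows)) dW[ly$maskRows, ] <- 0
  dM <- tcrossprod(dyM, Wm)
  if (ly$k == 1L) {
    dx <- array(dM, c(H, W, ly$cin))
  } else {
    p <- ly$dil * (ly$k - 1L) %/% 2L
    dxp <- array(0, c(H + 2L * p, W + 2L * p, ly$cin))
    t <- 0L
    for (a in seq_len(ly$k)) {
      rows <- seq.int((a - 1L) * ly$dil + 1L, length.out = H)
      for (b in seq_len(ly$k)) {
        t <- t + 1L
        cols <- seq.int((b - 1L) * ly$dil + 1L, length.out = W)
        blk <- array(dM[, ((t - 1L) * ly$cin + 1L):(t * ly$cin)],
                     c(H, W, ly$cin))
        dxp[rows, cols, ] <- dxp[rows, cols, ] + blk
      }
    }
    # adjoint of zero padding: crop
    dx <- dxp[p + seq_len(H), p + seq_len(W), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

reluF <- function(x) {
  x[x < 0] <- 0
  x
}
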