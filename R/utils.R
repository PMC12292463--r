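# Internal numeric helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Index map implementing mirror ("reflect", no edge duplication) padding of
# size p on an axis of length n: padded axis -> source index. Requires p < n.
reflectMap <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  stopifnot(p < n)
  c(seq(p + 1L, 2L), seq_len(n), seq(n - 1L, n - p))
}

# Reflect-pad a matrix by (pr, pc) on each side.
padReflect <- function(x, pr, pc = pr) {
  x[reflectMap(nrow(x), pr), reflectMap(ncol(x), pc), drop = FALSE]
}

gaussianKernel1D <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a matrix with reflect borders.
smoothGaussian2D <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussianKernel1D(sigma)
  r <- (length(k) - 1L) / 2L
  if (r >= nrow(x) || r >= ncol(x))
    stop("smoothing kernel larger than image")
  xp <- padReflect(x, r, r)
  # rows
  acc <- matrix(0, nrow(x), ncol(xp))
  for (i in seq_along(k))
    acc <- acc + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k))
    out <- out + k[i] * acc[, i:(i + ncol(x) - 1L), drop = FALSE]
  out
}

#' Peak signal-to-noise ratio
#'
#' PSNR of `x` against a reference, in dB. The peak is the reference maximum
#' unless given. Identical images return the cap (default 120 dB) rather
#' than Inf so that downstream summaries stay finite.
#'
#' @param x,reference numeric arrays of identical shape.
#' @param peak signal peak; defaults to `max(reference)`.
#' @param cap value returned when the MSE underflows.
#' @return scalar PSNR in dB.
#' @export
psnr <- function(x, reference, peak = max(reference), cap = 120) {
  stopifnot(all(dim(x) == dim(reference)) || length(x) == length(reference))
  mse <- mean((as.numeric(x) - as.numeric(reference))^2)
  if (mse <= .Machine$double.eps * peak^2) return(cap)
  min(cap, 10 * log10(peak^2 / mse))
}

# Robust per-slice intensity scale (99.9th percentile), guarded away from 0.
robustScale <- function(x, q = 0.999) {
  s <- as.numeric(stats::quantile(x, q, names = FALSE))
  if (!is.finite(s) || s <= 0) s <- max(x, 1e-12)
  max(s, 1e-12)
}

# Cheap content fingerprint for provenance records (not cryptographic).
contentFingerprint <- function(x) {
  v <- as.numeric(x)
  sprintf("n%d_s%.8g_r%.8g_%.8g", length(v), sum(v), min(v), max(v))
}
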