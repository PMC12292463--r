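# Plug-and-play ADMM: couples the data-fidelity term against the trained
# blind-spot denoiser acting as the image prior.

#' ADMM x-update
#'
#' Exact minimizer of the x-subproblem
#' \eqn{\tfrac12\|y-x\|^2 + \tfrac{\rho}{2}\|x-z+u\|^2}:
#' \code{x = (y + rho * (z - u)) / (1 + rho)} (rule "scaled"). The
#' typographically literal alternative \code{(y + rho*z - u) / (1 + rho)}
#' is selectable for auditability.
#'
#' @param y,z,u numeric arrays of identical shape.
#' @param rho positive weighting parameter.
#' @param rule "scaled" (default) or "literal".
#' @return the updated x.
#' @export
xUpdate <- function(y, z, u, rho, rule = c("scaled", "literal")) {
  rule <- match.arg(rule)
  if (rho <= 0) stop("rho must be > 0")
  stopifnot(length(y) == length(z), length(y) == length(u))
  if (rule == "scaled") (y + rho * (z - u)) / (1 + rho)
  else (y + rho * z - u) / (1 + rho)
}

# Apply either a DenoiserModel or a plain function (test stub) as D_sigma.
applyDenoiser <- function(model, image, seed) {
  if (is.function(model)) model(image) else denoiseAPBSN(model, image, seed)
}

#' Plug-and-play denoising (PnP-BSN)
#'
#' Runs K ADMM iterations of
#' \deqn{\arg\min_{x,z} \tfrac12\|y - x\|^2 + \tfrac{\rho}{2}\|x - z\|^2
#'   \quad \mathrm{s.t.}\ z = D_\sigma(x + u),}
#' with the trained blind-spot denoiser as \eqn{D_\sigma}:
#' initialization \eqn{u^0 = 0,\ z^0 = D_\sigma(y)}; per iteration
#' \eqn{x \leftarrow (y + \rho(z-u))/(1+\rho)},
#' \eqn{z \leftarrow D_\sigma(x+u)}, \eqn{u \leftarrow u + x - z}. Exactly K
#' iterations are run (no convergence test); the data-fidelity term pulls
#' the result toward the original noisy image, balancing the denoiser
#' prior.
#'
#' @param y 2D noisy matrix.
#' @param model a trained \linkS4class{DenoiserModel}, or a function
#'   \code{image -> image} used directly as the denoiser (useful for
#'   analysis stubs).
#' @param cfg a \linkS4class{PnPConfig}.
#' @return the final x, with attribute \code{residualHistory} holding the
#'   per-iteration \eqn{\|x - z\|} values.
#' @export
pnpDenoise <- function(y, model, cfg = pnpConfig()) {
  stopifnot(is(cfg, "PnPConfig"))
  rho <- cfg@rho
  u <- matrix(0, nrow(y), ncol(y))
  z <- applyDenoiser(model, y, cfg@seed)
  x <- y
  resid <- numeric(cfg@nIters)
  for (k in seq_len(cfg@nIters)) {
    x <- xUpdate(y, z, u, rho, rule = cfg@xUpdateRule)
    z <- if (cfg@zRule == "standard")
      applyDenoiser(model, x + u, cfg@seed + k)
    else applyDenoiser(model, x, cfg@seed + k) + u
    u <- u + x - z
    if (!all(is.finite(x)) || !all(is.finite(z)))
      stop(sprintf("non-finite intermediate at iteration %d", k))
    resid[k] <- sqrt(sum((x - z)^2))
  }
  attr(x, "residualHistory") <- resid
  x
}
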