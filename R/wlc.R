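#' Worm-like-chain force at a given extension
#'
#' Interpolation formula for the entropic elasticity of a semiflexible
#' polymer: the force required to hold a chain of persistence length
#' `Lp` and contour length `Lc` at end-to-end extension `x`,
#'
#' \deqn{F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4}\left(1 -
#'   \frac{x}{L_c}\right)^{-2} - \frac{1}{4} + \frac{x}{L_c}\right].}
#'
#' The force vanishes at zero extension, grows linearly at small
#' extension and diverges as \eqn{x \to L_c}; it is strictly increasing
#' on `[0, Lc)`.
#'
#' @param x Extension in nm (vectorised). Must satisfy `0 <= x < Lc`.
#' @param Lp Persistence length in nm, `0 < Lp < Lc`.
#' @param Lc Contour length in nm.
#' @param temperature Absolute temperature in K (default 298, room
#'   temperature).
#' @return Force in pN, same length as `x`.
#' @seealso [wlc_extension()] for the numerical inverse.
#' @export
#' @examples
#' wlc_force(0, Lp = 0.38, Lc = 33)            # 0
#' wlc_force(16.5, Lp = 0.38, Lc = 33)          # 1.25 * kBT / Lp ~ 13.5 pN
wlc_force <- function(x, Lp, Lc, temperature = 298) {
  stopifnot(is.numeric(x), is.numeric(Lp), is.numeric(Lc),
            length(Lp) == 1, length(Lc) == 1)
  if (!(Lp > 0 && Lc > Lp)) {
    abort("`Lp` and `Lc` must satisfy 0 < Lp < Lc.", class = "smc_param_error")
  }
  if (any(x < 0) || any(x >= Lc)) {
    abort("extension `x` must lie in [0, Lc): the model diverges at x = Lc.",
          class = "smc_domain_error")
  }
  t <- x / Lc
  (kBT(temperature) / Lp) * (0.25 * (1 - t)^-2 - 0.25 + t)
}

#' Extension of a worm-like chain at a given force
#'
#' Numerical inverse of [wlc_force()]: the extension at which the chain
#' tension equals `force`. Solved by bisection on `[0, Lc)`; the forward
#' model is strictly monotonic so the root is unique.
#'
#' @param force Force in pN (vectorised), `>= 0`.
#' @inheritParams wlc_force
#' @param tol Absolute tolerance on the extension in nm.
#' @return Extension in nm.
#' @export
wlc_extension <- function(force, Lp, Lc, temperature = 298, tol = 1e-9) {
  stopifnot(is.numeric(force), all(force >= 0))
  vapply(force, function(f) {
    if (f == 0) return(0)
    lo <- 0
    hi <- Lc * (1 - 1e-12)
    # expandable upper guard not needed: F -> Inf as x -> Lc
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (wlc_force(mid, Lp, Lc, temperature) < f) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}
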