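#' Parameters for synthetic force-distance curve generation
#'
#' Bundles and validates the generator settings for [sim_fd_curves()].
#' The defaults describe a tethered single-molecule pulling assay:
#' a PEG tether of contour length ~33 +/- 5 nm (polydispersity),
#' instrument force noise of ~10 pN, a retraction speed of 500 nm/s and
#' a specific-event yield of ~9% of approach-retraction cycles, with a
#' small fraction of short-range nonspecific adhesion curves.
#'
#' @param n_curves Number of curves to generate.
#' @param rupture_mean,rupture_sd Mean and SD (pN) of the true rupture
#'   force distribution (normal, truncated at > 0).
#' @param lc_mean,lc_sd Mean and SD (nm) of the tether contour length
#'   distribution (normal; must keep `lc_sd < lc_mean`).
#' @param lp Tether persistence length in nm used to render the
#'   worm-like-chain ramp.
#' @param temperature Temperature in K.
#' @param specific_fraction Fraction of curves carrying one specific
#'   worm-like-chain unbinding event.
#' @param nonspecific_fraction Fraction of curves carrying a short-range
#'   (< 10 nm) adhesion peak instead; the remainder are noise-only.
#' @param noise_sd Gaussian force noise SD in pN added to every sample.
#' @param retraction_speed Retraction speed in nm/s (metadata; with
#'   `sampling_rate` it sets the distance step).
#' @param sampling_rate Force sampling rate in Hz.
#' @param x_max Maximum tip-surface separation in nm.
#' @return A validated list of class `fd_params`.
#' @seealso [fd_preset()] for the hairpin-monomer (H-M) and
#'   hairpin-hairpin (H-H) study presets.
#' @export
fd_params <- function(n_curves = 2000,
                      rupture_mean = 164, rupture_sd = 17,
                      lc_mean = 33, lc_sd = 5,
                      lp = 0.38,
                      temperature = 298,
                      specific_fraction = 0.09,
                      nonspecific_fraction = 0.05,
                      noise_sd = 10,
                      retraction_speed = 500,
                      sampling_rate = 5000,
                      x_max = 60) {
  if (specific_fraction < 0 || nonspecific_fraction < 0 ||
      specific_fraction + nonspecific_fraction > 1) {
    abort("specific_fraction + nonspecific_fraction must lie in [0, 1].",
          class = "smc_param_error")
  }
  if (!(lc_sd < lc_mean)) {
    abort("`lc_sd` must be smaller than `lc_mean`.", class = "smc_param_error")
  }
  scales <- c(n_curves = n_curves, rupture_mean = rupture_mean,
              lc_mean = lc_mean, lp = lp, temperature = temperature,
              retraction_speed = retraction_speed,
              sampling_rate = sampling_rate, x_max = x_max)
  if (any(scales <= 0)) {
    abort(paste0("all scale parameters must be positive; offending: ",
                 paste(names(scales)[scales <= 0], collapse = ", ")),
          class = "smc_param_error")
  }
  if (rupture_sd < 0 || lc_sd < 0 || noise_sd < 0) {
    abort("standard deviations must be >= 0.", class = "smc_param_error")
  }
  structure(
    list(n_curves = as.integer(n_curves), rupture_mean = rupture_mean,
         rupture_sd = rupture_sd, lc_mean = lc_mean, lc_sd = lc_sd,
         lp = lp, temperature = temperature,
         specific_fraction = specific_fraction,
         nonspecific_fraction = nonspecific_fraction,
         noise_sd = noise_sd, retraction_speed = retraction_speed,
         sampling_rate = sampling_rate, x_max = x_max),
    class = "fd_params")
}

#' Study presets for the force-distance generator
#'
#' Ground-truth parameter sets for the two probing geometries of the
#' hairpin/monomer assembly study: hairpin-monomer (`"HM"`, rupture
#' force 164 +/- 17 pN, 180 specific events out of 2000 cycles) and
#' hairpin-hairpin (`"HH"`, 100 +/- 6 pN, 175 of 2000). Both use the
#' PEG tether contour length 33 +/- 5 nm.
#'
#' @param kind `"HM"` or `"HH"`.
#' @param ... Overrides forwarded to [fd_params()].
#' @return An `fd_params` object.
#' @export
fd_preset <- function(kind = c("HM", "HH"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    HM = list(rupture_mean = 164, rupture_sd = 17, specific_fraction = 0.09),
    HH = list(rupture_mean = 100, rupture_sd = 6,  specific_fraction = 0.0875))
  do.call(fd_params, utils::modifyList(defaults, list(...)))
}

# normal draw truncated below at `lower` by redraw
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Simulate a batch of force-distance retraction curves
#'
#' Generates `n_curves` retraction traces on a regular distance grid.
#' `round(n_curves * specific_fraction)` of them carry one specific
#' unbinding event: the force follows the worm-like-chain ramp
#' ([wlc_force()]) of a tether with contour length drawn from
#' `Normal(lc_mean, lc_sd)` up to the extension where the chain tension
#' reaches the drawn rupture force (the ramp endpoint is found by
#' numerically inverting the force law with [wlc_extension()]), then
#' drops to baseline. Nonspecific curves carry a triangular adhesion
#' peak confined to < 10 nm from contact; the rest are noise-only.
#' Ground-truth labels are attached for downstream validation.
#'
#' @param params An [fd_params()] object.
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @return A tibble of class `fd_curves` with one row per curve:
#'   `curve_id`, `type` (`"specific"`, `"nonspecific"`, `"none"`),
#'   ground truth `fr_true`, `lc_true`, `x_rupture_true` (NA for
#'   non-specific rows) and a `curve` list-column of
#'   `tibble(distance_nm, force_pN)`. Generator parameters are stored in
#'   `attr(, "params")`.
#' @export
#' @examples
#' curves <- sim_fd_curves(fd_preset("HM", n_curves = 20), seed = 1)
#' table(curves$type)
sim_fd_curves <- function(params, seed = 1) {
  stopifnot(inherits(params, "fd_params"))
  set.seed(seed)
  p <- params
  n <- p$n_curves
  n_spec <- round(n * p$specific_fraction)
  n_nonspec <- round(n * p$nonspecific_fraction)
  type <- rep("none", n)
  type[seq_len(n_spec)] <- "specific"
  if (n_nonspec > 0) type[n_spec + seq_len(n_nonspec)] <- "nonspecific"
  type <- sample(type)

  dx <- p$retraction_speed / p$sampling_rate
  x <- seq(0, p$x_max, by = dx)

  fr_true <- rep(NA_real_, n)
  lc_true <- rep(NA_real_, n)
  x_rup <- rep(NA_real_, n)
  is_spec <- type == "specific"
  if (n_spec > 0) {
    fr_true[is_spec] <- rnorm_trunc(n_spec, p$rupture_mean, p$rupture_sd)
    lc_true[is_spec] <- rnorm_trunc(n_spec, p$lc_mean, p$lc_sd,
                                    lower = 2 * p$lp)
  }

  curves <- vector("list", n)
  for (i in seq_len(n)) {
    f <- if (p$noise_sd > 0) rnorm(length(x), 0, p$noise_sd) else numeric(length(x))
    if (type[i] == "specific") {
      xr <- wlc_extension(fr_true[i], p$lp, lc_true[i], p$temperature)
      x_rup[i] <- xr
      on <- x <= xr
      f[on] <- f[on] + wlc_force(x[on], p$lp, lc_true[i], p$temperature)
    } else if (type[i] == "nonspecific") {
      amp <- rnorm_trunc(1, 60, 15)
      xp <- runif(1, 2, 6)
      on <- x <= xp
      f[on] <- f[on] + amp * x[on] / xp
    }
    curves[[i]] <- tibble(distance_nm = x, force_pN = f)
  }

  out <- tibble(
    curve_id = sprintf("curve_%04d", seq_len(n)),
    type = type, fr_true = fr_true, lc_true = lc_true,
    x_rupture_true = x_rup, curve = curves)
  attr(out, "params") <- p
  attr(out, "seed") <- seed
  class(out) <- c("fd_curves", class(out))
  out
}
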