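#' Plot force-distance curves
#'
#' Faceted retraction traces; specific curves show the worm-like-chain
#' ramp ending in the rupture drop.
#'
#' @param object An `fd_curves` tibble from [sim_fd_curves()].
#' @param n Maximum number of curves to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fd_curves <- function(object, n = 6, ...) {
  idx <- seq_len(min(n, nrow(object)))
  df <- tidyr::unnest(object[idx, c("curve_id", "type", "curve")],
                      cols = "curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_nm,
                                   y = .data$force_pN)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~curve_id) +
    ggplot2::labs(x = "tip-surface separation (nm)", y = "force (pN)")
}

#' Plot a Gaussian histogram fit
#'
#' The binned values with the fitted Gaussian overlaid, the standard
#' presentation of rupture-force and contour-length histograms.
#'
#' @param object A `gaussian_fit` from [fit_gaussian_hist()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaussian_fit <- function(object, ...) {
  h <- object$histogram
  xg <- seq(min(h$mid), max(h$mid), length.out = 200)
  amp <- max(h$count)
  curve <- tibble(x = xg,
                  y = amp * exp(-(xg - object$mean)^2 / (2 * object$sd^2)))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey70",
                      colour = "grey30") +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = "value", y = "count")
}

#' Plot a free-energy surface
#'
#' Raster of \eqn{\Delta G(V_1, V_2)} in kBT; unpopulated bins are
#' blank.
#'
#' @param object An `fep_grid` from [free_energy_surface()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fep_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$deltaG)),
                  ggplot2::aes(x = .data$V1, y = .data$V2,
                               fill = .data$deltaG)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * G ~ (k[B] * T)),
                                  direction = -1) +
    ggplot2::labs(x = "V1", y = "V2")
}

#' Plot a pulling trace
#'
#' Spring force versus anchor separation with the rupture point
#' marked.
#'
#' @param object A `pulling_trace` from [mc_pull()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pulling_trace <- function(object, ...) {
  df <- object$trace
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$separation,
                                        y = .data$force)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "anchor separation (nm)", y = "spring force (pN)")
  if (!is.na(object$rupture_sweep)) {
    p <- p + ggplot2::geom_vline(
      xintercept = df$separation[object$rupture_sweep],
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a topograph
#'
#' Height map in nm with an AFM-style colour scale.
#'
#' @param object A `topograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.topograph <- function(object, ...) {
  h <- object$heights
  df <- tibble(
    x = rep((seq_len(nrow(h)) - 0.5) * object$pixel_nm, times = ncol(h)),
    y = rep((seq_len(ncol(h)) - 0.5) * object$pixel_nm, each = nrow(h)),
    height = as.vector(h))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "goldenrod1",
                                 name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}
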