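#' Detect the specific unbinding event in a retraction curve
#'
#' Baseline-corrects the trace (median of the final `baseline_frac` of
#' samples, the far-from-surface region), estimates the noise scale from
#' the same region, and scans a lightly median-smoothed copy for an
#' abrupt drop back to baseline that exceeds `k_sigma` noise SDs.
#' Short-range adhesion (drops closer to contact than `min_distance`)
#' is ignored. When several drops qualify the one at the largest
#' distance is taken (the last unbinding of a serial tether). The drop
#' is then localised on the raw trace and the rupture distance is
#' placed midway between the last on-ramp and first post-drop sample.
#'
#' @param curve A data frame with columns `distance_nm` and `force_pN`
#'   (one retraction trace), e.g. one element of the `curve` list-column
#'   of [sim_fd_curves()] output.
#' @param k_sigma Detection threshold in units of the baseline noise SD.
#' @param min_distance Minimum rupture distance in nm; anything closer
#'   is treated as nonspecific adhesion.
#' @param min_force Minimum absolute drop in pN (guards against a noise
#'   SD estimate of ~0 on synthetic noise-free traces).
#' @param x_min_fit Lower distance bound (nm) of the returned ramp
#'   segment; the first couple of nm are contaminated by contact.
#' @return A one-row tibble with `x_rupture` (nm), `drop_pN`, and a
#'   `segment` list-column holding the baseline-corrected monotonic ramp
#'   (`distance_nm`, `force_pN`) up to the rupture point, or a zero-row
#'   tibble when no qualifying drop exists (the curve is a non-event).
#' @export
detect_rupture <- function(curve, k_sigma = 6, min_distance = 10,
                           min_force = 30, x_min_fit = 2) {
  stopifnot(all(c("distance_nm", "force_pN") %in% names(curve)))
  x <- curve$distance_nm
  f <- curve$force_pN
  n <- length(x)
  empty <- tibble(x_rupture = numeric(), drop_pN = numeric(),
                  segment = list())
  if (n < 50) return(empty)

  tail_idx <- seq.int(floor(n * 0.8), n)
  baseline <- median(f[tail_idx])
  sigma <- mad(f[tail_idx])
  f <- f - baseline

  sm <- stats::runmed(f, 5)
  thr <- max(k_sigma * sigma, min_force)

  lag <- 2L
  i_ok <- which(x >= min_distance & seq_len(n) <= n - lag)
  drop2 <- sm[i_ok] - sm[i_ok + lag]
  cand <- i_ok[drop2 > thr & sm[i_ok] > thr]
  if (length(cand) == 0) return(empty)

  k <- max(cand)  # last unbinding
  # localise the single-sample drop on the raw trace
  win <- max(1L, k - 2L):min(n - 1L, k + 3L)
  j <- win[which.max(f[win] - f[win + 1L])]
  x_rupture <- (x[j] + x[j + 1L]) / 2
  drop_pN <- f[j] - f[j + 1L]

  seg <- which(x >= x_min_fit & x <= x[j])
  if (length(seg) < 10) return(empty)
  tibble(x_rupture = x_rupture, drop_pN = drop_pN,
         segment = list(tibble(distance_nm = x[seg], force_pN = f[seg])))
}

#' Fit the worm-like-chain model to a rupture ramp
#'
#' Nonlinear least squares of the worm-like-chain force law
#' ([wlc_force()]) on the detected ramp segment. The persistence length
#' is by default a free parameter bounded in `lp_bounds` (PEG tether
#' stiffness is not known a priori); pass a single number as `lp` to fix
#' it. The rupture force `Fr` is the fitted model force evaluated at the
#' detected rupture distance, which is robust to single-sample noise
#' spikes at the drop.
#'
#' @param segment Data frame with `distance_nm`, `force_pN`: the ramp
#'   below the rupture point (>= 10 points).
#' @param x_rupture Rupture distance in nm where `Fr` is evaluated.
#' @param temperature Temperature in K.
#' @param lp `NULL` to fit the persistence length freely, or a fixed
#'   value in nm.
#' @param lp_bounds Bounds (nm) for a free persistence-length fit.
#' @param curve_id Optional label carried into the result.
#' @return An object of class `wlc_fit`: list with `Fr`, `Lc`, `Lp`,
#'   `x_rupture`, `rss` (pN^2), `n_points`, `converged`, `curve_id`.
#'   Errors of class `smc_fit_error` on non-convergence or degenerate
#'   segments.
#' @export
fit_wlc <- function(segment, x_rupture, temperature = 298,
                    lp = NULL, lp_bounds = c(0.1, 2), curve_id = NA_character_) {
  stopifnot(all(c("distance_nm", "force_pN") %in% names(segment)))
  x <- segment$distance_nm
  f <- segment$force_pN
  if (length(x) < 10) {
    abort("segment must contain >= 10 points below the rupture.",
          class = "smc_fit_error")
  }
  if (sd(f) < 1e-12) {
    abort("flat segment: no force ramp to fit.", class = "smc_fit_error")
  }
  kT <- kBT(temperature)
  xmax <- max(x)
  lc_start <- max(xmax / 0.85, xmax + 1)

  fit <- tryCatch({
    if (is.null(lp)) {
      minpack.lm::nlsLM(
        f ~ (kT / Lp) * (0.25 * (1 - x / Lc)^-2 - 0.25 + x / Lc),
        start = list(Lp = 0.38, Lc = lc_start),
        lower = c(lp_bounds[1], xmax + 1e-3),
        upper = c(lp_bounds[2], 20 * xmax),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        f ~ (kT / lp) * (0.25 * (1 - x / Lc)^-2 - 0.25 + x / Lc),
        start = list(Lc = lc_start),
        lower = xmax + 1e-3, upper = 20 * xmax,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort(paste0("worm-like-chain fit failed: ", conditionMessage(e)),
          class = "smc_fit_error")
  })

  cf <- coef(fit)
  Lp_hat <- if (is.null(lp)) unname(cf["Lp"]) else lp
  Lc_hat <- unname(cf["Lc"])
  if (!(Lp_hat < Lc_hat)) {
    abort("fit violated Lp < Lc.", class = "smc_fit_error")
  }
  Fr <- wlc_force(min(x_rupture, Lc_hat * (1 - 1e-9)), Lp_hat, Lc_hat,
                  temperature)
  structure(
    list(Fr = Fr, Lc = Lc_hat, Lp = Lp_hat, x_rupture = x_rupture,
         rss = sum(resid(fit)^2), n_points = length(x),
         converged = fit$convInfo$isConv %||% TRUE, curve_id = curve_id),
    class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf(
    "Worm-like-chain fit: Fr = %.1f pN, Lc = %.1f nm, Lp = %.2f nm (n = %d)\n",
    x$Fr, x$Lc, x$Lp, x$n_points))
  invisible(x)
}

#' @rdname fit_wlc
#' @param x A `wlc_fit` object.
#' @param ... Unused.
#' @export
tidy.wlc_fit <- function(x, ...) {
  tibble(term = c("Fr", "Lc", "Lp"),
         estimate = c(x$Fr, x$Lc, x$Lp),
         unit = c("pN", "nm", "nm"))
}

#' @rdname fit_wlc
#' @export
glance.wlc_fit <- function(x, ...) {
  tibble(Fr = x$Fr, Lc = x$Lc, Lp = x$Lp, x_rupture = x$x_rupture,
         rss = x$rss, n_points = x$n_points, converged = x$converged)
}

#' Filter fitted events for tether specificity
#'
#' Keeps events whose fitted contour length falls inside the window
#' expected for the PEG tether (default 23-43 nm, i.e. 33 +/- 2 SD of
#' the 5 nm polydispersity) and whose rupture force exceeds the
#' instrument noise floor (10-20 pN in the control experiments).
#'
#' @param events A tibble of fitted events with columns `Fr` and `Lc`
#'   (e.g. from [analyze_force_curves()]).
#' @param lc_window Length-2 numeric, contour-length window in nm.
#' @param noise_floor Minimum rupture force in pN.
#' @return The kept rows, with `attr(, "n_kept")` and
#'   `attr(, "n_rejected")` counts.
#' @export
filter_specific <- function(events, lc_window = c(23, 43), noise_floor = 20) {
  stopifnot(length(lc_window) == 2, lc_window[1] < lc_window[2])
  if (nrow(events) == 0) {
    out <- events
  } else {
    out <- dplyr::filter(events,
                         .data$Lc >= lc_window[1], .data$Lc <= lc_window[2],
                         .data$Fr > noise_floor)
  }
  attr(out, "n_kept") <- nrow(out)
  attr(out, "n_rejected") <- nrow(events) - nrow(out)
  out
}

#' Least-squares Gaussian fit to a histogram
#'
#' Bins the values (Freedman-Diaconis width by default) and fits a
#' scaled Gaussian to the bin counts by nonlinear least squares: the
#' estimator used on rupture-force and contour-length histograms to
#' locate the most probable value.
#'
#' @param values Numeric vector (>= 20 values).
#' @param bin_width Histogram bin width in the units of `values`;
#'   default Freedman-Diaconis.
#' @return Object of class `gaussian_fit`: `mean`, `sd`, `n`,
#'   `bin_width`, `rss`, `relative_rss` (RSS over total sum of squared
#'   counts, high for poorly Gaussian input, e.g. bimodal samples).
#' @export
fit_gaussian_hist <- function(values, bin_width = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 20) {
    abort("need >= 20 values for a histogram fit.", class = "smc_fit_error")
  }
  if (is.null(bin_width)) {
    bin_width <- 2 * IQR(values) / length(values)^(1 / 3)
    if (bin_width <= 0) {
      abort("degenerate sample: zero spread.", class = "smc_fit_error")
    }
  }
  breaks <- seq(min(values) - bin_width / 2,
                max(values) + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0
  if (sum(keep) < 3) {
    abort("fewer than 3 populated bins: cannot fit a Gaussian.",
          class = "smc_fit_error")
  }
  xb <- h$mids
  yb <- h$counts
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yb ~ A * exp(-(xb - mu)^2 / (2 * s^2)),
      start = list(A = max(yb), mu = mean(values), s = sd(values)),
      lower = c(0, min(values), bin_width / 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("Gaussian histogram fit failed: ",
                                     conditionMessage(e)),
                              class = "smc_fit_error"))
  cf <- coef(fit)
  rss <- sum(resid(fit)^2)
  structure(
    list(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])),
         n = length(values), bin_width = bin_width,
         rss = rss, relative_rss = rss / sum(yb^2),
         histogram = tibble(mid = xb, count = yb)),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian histogram fit: mean = %.3g, sd = %.3g (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' @rdname fit_gaussian_hist
#' @param x A `gaussian_fit` object.
#' @param ... Unused.
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(term = c("mean", "sd"), estimate = c(x$mean, x$sd))
}

#' @rdname fit_gaussian_hist
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, n = x$n, bin_width = x$bin_width,
         rss = x$rss, relative_rss = x$relative_rss)
}

#' Combine replicate histogram fits
#'
#' Arithmetic mean and SD of the per-replicate fitted means, the way
#' independent repeat experiments are summarised (mean +/- SD over
#' three replicates).
#'
#' @param results A list of `gaussian_fit` objects, or a numeric vector
#'   of replicate means. At least 2 replicates.
#' @return Tibble with `mean`, `sd`, `n_replicates`.
#' @export
aggregate_replicates <- function(results) {
  means <- if (is.numeric(results)) results
           else map_dbl(results, function(r) r$mean)
  if (length(means) < 2) {
    abort("need >= 2 replicates to aggregate.", class = "smc_param_error")
  }
  tibble(mean = mean(means), sd = sd(means), n_replicates = length(means))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two groups of measured values (e.g. rupture forces of the
#' two probing geometries) with the two-sample KS test.
#'
#' @param group_a,group_b Numeric vectors, each >= 20 values.
#' @return Tibble with `statistic` (D) and `p_value`.
#' @export
ks_compare <- function(group_a, group_b) {
  if (length(group_a) < 20 || length(group_b) < 20) {
    abort("both groups need >= 20 values.", class = "smc_param_error")
  }
  kt <- suppressWarnings(ks.test(group_a, group_b, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Full force-spectroscopy analysis of a curve batch
#'
#' Runs the rupture pipeline over a batch of curves: event detection
#' ([detect_rupture()]), worm-like-chain fitting ([fit_wlc()]),
#' contour-length / noise-floor specificity filtering
#' ([filter_specific()]), and Gaussian histogram fits of the rupture
#' forces and contour lengths.
#'
#' @param curves An `fd_curves` tibble from [sim_fd_curves()], or any
#'   tibble with `curve_id` and a `curve` list-column of
#'   (`distance_nm`, `force_pN`) data frames.
#' @param lc_window,noise_floor Passed to [filter_specific()].
#' @param temperature,lp Passed to [fit_wlc()].
#' @param ... Passed to [detect_rupture()].
#' @return Object of class `force_analysis`: list with `events` (kept
#'   events tibble: `curve_id`, `Fr`, `Lc`, `Lp`, `x_rupture`, `rss`),
#'   `events_all` (pre-filter), `force_fit` and `lc_fit`
#'   (`gaussian_fit`), `n_curves`, `yield` (detected events / curves).
#' @export
#' @examples
#' curves <- sim_fd_curves(fd_preset("HM", n_curves = 60), seed = 1)
#' res <- analyze_force_curves(curves)
#' glance(res$force_fit)
analyze_force_curves <- function(curves, lc_window = c(23, 43),
                                 noise_floor = 20, temperature = 298,
                                 lp = NULL, ...) {
  stopifnot("curve" %in% names(curves), "curve_id" %in% names(curves))
  rows <- vector("list", nrow(curves))
  for (i in seq_len(nrow(curves))) {
    det <- detect_rupture(curves$curve[[i]], ...)
    if (nrow(det) == 0) next
    ev <- tryCatch(
      fit_wlc(det$segment[[1]], det$x_rupture[1], temperature = temperature,
              lp = lp, curve_id = curves$curve_id[i]),
      smc_fit_error = function(e) NULL)
    if (is.null(ev) || !ev$converged) next
    rows[[i]] <- glance(ev) |> mutate(curve_id = curves$curve_id[i])
  }
  events_all <- bind_rows(rows)
  if (nrow(events_all) == 0) {
    abort("no rupture events detected in the batch.", class = "smc_fit_error")
  }
  events <- filter_specific(events_all, lc_window, noise_floor)
  force_fit <- fit_gaussian_hist(events$Fr)
  lc_fit <- fit_gaussian_hist(events$Lc)
  structure(
    list(events = events, events_all = events_all,
         force_fit = force_fit, lc_fit = lc_fit,
         n_curves = nrow(curves), yield = nrow(events) / nrow(curves)),
    class = "force_analysis")
}

#' @export
print.force_analysis <- function(x, ...) {
  cat(sprintf(
    paste0("Force-spectroscopy analysis: %d curves, %d specific events ",
           "(yield %.1f%%)\n  rupture force %.1f +/- %.1f pN, ",
           "contour length %.1f +/- %.1f nm\n"),
    x$n_curves, nrow(x$events), 100 * x$yield,
    x$force_fit$mean, x$force_fit$sd, x$lc_fit$mean, x$lc_fit$sd))
  invisible(x)
}

#' @rdname analyze_force_curves
#' @param x A `force_analysis` object.
#' @param ... Unused for the methods.
#' @export
glance.force_analysis <- function(x, ...) {
  tibble(n_curves = x$n_curves, n_events = nrow(x$events),
         yield = x$yield,
         force_mean = x$force_fit$mean, force_sd = x$force_fit$sd,
         lc_mean = x$lc_fit$mean, lc_sd = x$lc_fit$sd)
}

#' @rdname analyze_force_curves
#' @export
tidy.force_analysis <- function(x, ...) {
  x$events
}
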