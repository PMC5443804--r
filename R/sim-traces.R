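#' Parameters for synthetic fluorescence trace generation
#'
#' Settings for [sim_intensity_traces()]. The defaults emulate a
#' single-molecule TIRF lifetime assay: traces of a few minutes
#' recorded at 100 ms temporal resolution in which complex formation
#' appears as a one-step rise of intensity and dissociation as a
#' one-step fall, so the burst duration (dwell) is the complex
#' lifetime. True dwells are lognormal; the generator takes the
#' distribution mean `dwell_mean_ms` and shape `dwell_sigma` and sets
#' \eqn{\mu = \ln m - \sigma^2/2}.
#'
#' @param n_traces Number of traces.
#' @param frame_ms Frame duration in ms (temporal resolution).
#' @param duration_s Trace duration in s; `duration_s * 1000 / frame_ms`
#'   must be integral.
#' @param dwell_mean_ms Mean of the lognormal dwell distribution (ms).
#' @param dwell_sigma Lognormal shape parameter (>= 0).
#' @param burst_rate Mean burst rate per trace in events/s (Poisson
#'   counts); ignored when `n_events` is given.
#' @param n_events Optional exact total number of bursts to inject,
#'   spread evenly over the traces.
#' @param signal_level Burst amplitude in arbitrary units.
#' @param background_sd Gaussian background noise SD (a.u.).
#' @return Validated list of class `trace_params`.
#' @export
trace_params <- function(n_traces = 30, frame_ms = 100, duration_s = 150,
                         dwell_mean_ms = 617, dwell_sigma = 0.8,
                         burst_rate = 0.05, n_events = NULL,
                         signal_level = 100, background_sd = 5) {
  if (frame_ms <= 0) abort("frame_ms must be > 0.", class = "smc_param_error")
  n_frames <- duration_s * 1000 / frame_ms
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    abort("duration_s * 1000 / frame_ms must be an integer frame count.",
          class = "smc_param_error")
  }
  if (dwell_sigma < 0) abort("dwell_sigma must be >= 0.",
                             class = "smc_param_error")
  stopifnot(n_traces >= 1, dwell_mean_ms > 0, signal_level > 0,
            background_sd >= 0, burst_rate >= 0)
  structure(
    list(n_traces = as.integer(n_traces), frame_ms = frame_ms,
         duration_s = duration_s, n_frames = as.integer(round(n_frames)),
         dwell_mean_ms = dwell_mean_ms, dwell_sigma = dwell_sigma,
         log_mu = log(dwell_mean_ms) - dwell_sigma^2 / 2,
         burst_rate = burst_rate, n_events = n_events,
         signal_level = signal_level, background_sd = background_sd),
    class = "trace_params")
}

#' Lifetime-assay presets
#'
#' Ground-truth dwell distributions of the two complexes in the
#' hairpin/monomer study: `"HM"` (mean lifetime 617 ms, n = 297 events)
#' and `"HH"` (344 ms, n = 274 events).
#'
#' @param kind `"HM"` or `"HH"`.
#' @param ... Overrides forwarded to [trace_params()].
#' @return A `trace_params` object.
#' @export
trace_preset <- function(kind = c("HM", "HH"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    HM = list(dwell_mean_ms = 617, n_events = 297),
    HH = list(dwell_mean_ms = 344, n_events = 274))
  do.call(trace_params, utils::modifyList(defaults, list(...)))
}

#' Simulate single-molecule fluorescence intensity traces
#'
#' Generates framed intensity traces with one-step bursts. Each burst
#' has a true dwell drawn from the lognormal distribution, quantized to
#' whole frames by rounding (minimum one frame; dwells shorter than one
#' frame are emitted but flagged sub-resolution). Bursts are placed
#' without overlap, never touching the first or last frame, with at
#' least a two-frame gap between bursts. Ground-truth dwells are
#' attached.
#'
#' @param params A [trace_params()] object.
#' @param seed Integer seed.
#' @return Tibble of class `intensity_traces` with `trace_id` and a
#'   `trace` list-column of `tibble(frame, intensity)`. The ground
#'   truth is in `attr(, "truth")`: `trace_id`, `start_frame`,
#'   `n_frames`, `dwell_true_ms`, `dwell_ms` (quantized),
#'   `sub_resolution`.
#' @export
#' @examples
#' tr <- sim_intensity_traces(trace_preset("HM", n_traces = 5,
#'                                         n_events = 20), seed = 1)
#' nrow(attr(tr, "truth"))
sim_intensity_traces <- function(params, seed = 1) {
  stopifnot(inherits(params, "trace_params"))
  set.seed(seed)
  p <- params
  nf <- p$n_frames

  if (!is.null(p$n_events)) {
    counts <- diff(floor(seq(0, p$n_events, length.out = p$n_traces + 1)))
  } else {
    counts <- stats::rpois(p$n_traces, p$burst_rate * p$duration_s)
  }

  traces <- vector("list", p$n_traces)
  truth <- vector("list", p$n_traces)
  for (i in seq_len(p$n_traces)) {
    intensity <- rnorm(nf, 0, p$background_sd)
    occupied <- rep(FALSE, nf)
    occupied[c(1:2, (nf - 1):nf)] <- TRUE  # keep clear of trace boundaries
    ev <- list()
    for (e in seq_len(counts[i])) {
      d_true <- if (p$dwell_sigma == 0) p$dwell_mean_ms
                else rlnorm(1, p$log_mu, p$dwell_sigma)
      k <- max(1L, as.integer(round(d_true / p$frame_ms)))
      placed <- FALSE
      for (try in 1:200) {
        s <- sample.int(nf - k + 1L, 1L)
        idx <- s:(s + k - 1L)
        pad <- max(1L, s - 2L):min(nf, s + k + 1L)  # 2-frame gap
        if (!any(occupied[pad])) {
          occupied[pad] <- TRUE
          intensity[idx] <- intensity[idx] + p$signal_level
          ev[[length(ev) + 1L]] <- tibble(
            start_frame = s, n_frames = k,
            dwell_true_ms = d_true, dwell_ms = k * p$frame_ms,
            sub_resolution = d_true < p$frame_ms)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        warn(sprintf("trace %d: burst %d could not be placed (trace full).",
                     i, e))
      }
    }
    traces[[i]] <- tibble(frame = seq_len(nf), intensity = intensity)
    truth[[i]] <- if (length(ev)) bind_rows(ev) |>
        mutate(trace_id = sprintf("trace_%03d", i), .before = 1) else NULL
  }

  out <- tibble(trace_id = sprintf("trace_%03d", seq_len(p$n_traces)),
                trace = traces)
  attr(out, "truth") <- bind_rows(truth)
  attr(out, "params") <- p
  attr(out, "seed") <- seed
  class(out) <- c("intensity_traces", class(out))
  out
}
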