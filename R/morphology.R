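#' Cross-section profile through a topograph
#'
#' Extracts the height profile along the straight line between two
#' pixel positions by bilinear interpolation, the way cross-sections
#' are read off AFM topographs to size individual aggregates. The
#' baseline is the median of the first and last 10% of profile
#' samples (the profile ends are assumed to sit on bare surface).
#'
#' @param topo A `topograph` object ([sim_topograph()] or
#'   [read_topograph()]).
#' @param p1,p2 Length-2 numeric pixel coordinates `(row, col)` of the
#'   endpoints (may be fractional); must differ and lie inside the
#'   grid.
#' @param n Number of samples along the segment (default one per
#'   pixel-length of the segment, at least 20).
#' @return Object of class `cross_section`: list with `profile`
#'   (tibble `position_nm`, `height_nm`), `peak_height` (nm, above
#'   baseline), `fwhm_nm` (full width at half maximum, NA when no
#'   peak), `baseline`.
#' @export
cross_section <- function(topo, p1, p2, n = NULL) {
  stopifnot(inherits(topo, "topograph"),
            length(p1) == 2, length(p2) == 2)
  if (all(p1 == p2)) {
    abort("cross-section endpoints must differ.", class = "smc_param_error")
  }
  h <- topo$heights
  nr <- nrow(h); nc <- ncol(h)
  if (any(c(p1, p2) < 1) || p1[1] > nr || p2[1] > nr ||
      p1[2] > nc || p2[2] > nc) {
    abort("endpoints must lie inside the grid.", class = "smc_param_error")
  }
  seg_px <- sqrt(sum((p2 - p1)^2))
  if (is.null(n)) n <- max(20L, ceiling(seg_px) + 1L)
  t <- seq(0, 1, length.out = n)
  ri <- p1[1] + t * (p2[1] - p1[1])
  ci <- p1[2] + t * (p2[2] - p1[2])

  # bilinear interpolation at fractional (row, col)
  r0 <- pmin(pmax(floor(ri), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(ci), 1L), nc - 1L)
  fr <- ri - r0
  fc <- ci - c0
  z <- h[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
       h[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
       h[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
       h[cbind(r0 + 1L, c0 + 1L)] * fr * fc

  pos <- t * seg_px * topo$pixel_nm
  n_end <- max(2L, ceiling(n * 0.1))
  baseline <- median(c(z[seq_len(n_end)], z[seq.int(n - n_end + 1L, n)]))
  zc <- z - baseline
  peak <- max(zc)
  fwhm <- NA_real_
  if (peak > 0) {
    half <- peak / 2
    above <- which(zc >= half)
    if (length(above) >= 1) {
      # linear interpolation of the half-max crossings around the run
      lo_i <- min(above); hi_i <- max(above)
      lo <- if (lo_i > 1) {
        pos[lo_i - 1] + (half - zc[lo_i - 1]) /
          (zc[lo_i] - zc[lo_i - 1]) * (pos[lo_i] - pos[lo_i - 1])
      } else pos[1]
      hi <- if (hi_i < n) {
        pos[hi_i] + (zc[hi_i] - half) /
          (zc[hi_i] - zc[hi_i + 1]) * (pos[hi_i + 1] - pos[hi_i])
      } else pos[n]
      fwhm <- hi - lo
    }
  }
  structure(list(profile = tibble(position_nm = pos, height_nm = z),
                 peak_height = peak, fwhm_nm = fwhm, baseline = baseline),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Cross-section: peak height %.2f nm, FWHM %.1f nm\n",
              x$peak_height, x$fwhm_nm))
  invisible(x)
}

#' Detect particles on a topograph
#'
#' Thresholds the height map at `baseline + min_height` and labels
#' connected components (8-connectivity, via `EBImage::bwlabel`).
#' Components smaller than `min_area_px` are dropped; components
#' touching the image border are flagged. Two overlapping aggregates
#' merge into a single region; this is deliberate, matching what a
#' height threshold can resolve.
#'
#' Per-particle height uses an apex estimate by default: the mean of
#' the region pixels within `2 * sigma_bg` of the region maximum on a
#' 3x3 median-filtered map (`sigma_bg` = MAD of the sub-threshold
#' background). A plain maximum (`method = "max"`) is biased upward on
#' flat-topped particles by the extreme-value statistics of the
#' surface roughness, so it is not the default.
#'
#' The baseline is a clipped median: the plain image median is biased
#' upward by whatever fraction of the surface the particles cover, so
#' it is refined by re-taking the median over pixels within 3 MAD of
#' it (two iterations), which rejects the feature pixels on a
#' mostly-empty surface.
#'
#' @param topo A `topograph` object.
#' @param min_height Detection threshold above baseline in nm.
#' @param min_area_px Minimum region area in pixels.
#' @param method `"apex"` (default) or `"max"`.
#' @return Tibble with one row per particle: `particle`, `area_px`,
#'   `height_nm` (above baseline), `row`, `col` (position of the
#'   maximum), `touches_border`.
#' @export
detect_particles <- function(topo, min_height = 0.5, min_area_px = 4,
                             method = c("apex", "max")) {
  stopifnot(inherits(topo, "topograph"), min_height > 0, min_area_px >= 1)
  method <- match.arg(method)
  h <- topo$heights
  baseline <- clipped_median(h)
  hb <- h - baseline
  mask <- hb > min_height
  empty <- tibble(particle = integer(), area_px = integer(),
                  height_nm = numeric(), row = integer(), col = integer(),
                  touches_border = logical())
  if (!any(mask)) return(empty)

  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(labels)
  dim(lab) <- dim(h)

  bg_vals <- hb[!mask]
  sigma_bg <- if (length(bg_vals) > 10) mad(bg_vals) else 0
  hs <- if (sigma_bg > 0) median_filter3(hb) else hb

  nr <- nrow(h); nc <- ncol(h)
  out <- list()
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id)
    if (length(idx) < min_area_px) next
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    vals <- hs[idx]
    imax <- which.max(vals)
    height <- if (method == "max") {
      max(hb[idx])
    } else {
      apex <- vals >= vals[imax] - 2 * sigma_bg
      mean(vals[apex])
    }
    out[[length(out) + 1L]] <- tibble(
      particle = id, area_px = length(idx), height_nm = height,
      row = rows[imax], col = cols[imax],
      touches_border = any(rows == 1L | rows == nr |
                           cols == 1L | cols == nc))
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |> mutate(particle = dplyr::row_number())
}

# background level robust to partial feature coverage: median re-taken
# over pixels within 3 MAD of the previous estimate
clipped_median <- function(h, iterations = 2) {
  b <- median(h)
  for (it in seq_len(iterations)) {
    s <- mad(h, center = b)
    keep <- abs(h - b) < 3 * max(s, 1e-12)
    if (any(keep)) b <- median(h[keep])
  }
  b
}

# 3x3 median filter with edge replication
median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[nr + 2, ] <- pad[nr + 1, ]
  pad[, 1] <- pad[, 2]; pad[, nc + 2] <- pad[, nc + 1]
  stack <- vapply(1:9, function(k) {
    dr <- (k - 1) %% 3; dc <- (k - 1) %/% 3
    as.vector(pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc)])
  }, numeric(nr * nc))
  out <- apply(stack, 1, median)
  dim(out) <- c(nr, nc)
  out
}

#' Particle-height statistics
#'
#' Mean and SD of per-particle heights, the summary used to
#' characterise aggregate morphology classes (e.g. globular aggregates
#' of 2.65 +/- 0.61 nm versus disk-shaped aggregates of
#' 0.85 +/- 0.08 nm).
#'
#' @param particles Tibble from [detect_particles()] (or any data
#'   frame with a `height_nm` column), n >= 1.
#' @param exclude_border Drop particles flagged `touches_border`.
#' @return Object of class `particle_stats`: `heights`, `mean`, `sd`,
#'   `n`.
#' @export
height_stats <- function(particles, exclude_border = TRUE) {
  if (exclude_border && "touches_border" %in% names(particles)) {
    particles <- dplyr::filter(particles, !.data$touches_border)
  }
  hts <- particles$height_nm
  if (length(hts) < 1) {
    abort("no particles to summarise.", class = "smc_param_error")
  }
  structure(list(heights = hts, mean = mean(hts),
                 sd = if (length(hts) > 1) sd(hts) else 0,
                 n = length(hts)),
            class = "particle_stats")
}

#' @export
print.particle_stats <- function(x, ...) {
  cat(sprintf("Particle heights: %.2f +/- %.2f nm (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' @rdname height_stats
#' @param x A `particle_stats` object.
#' @param ... Unused.
#' @export
glance.particle_stats <- function(x, ...) {
  tibble(mean = x$mean, sd = x$sd, n = x$n)
}

#' @rdname height_stats
#' @export
tidy.particle_stats <- function(x, ...) {
  tibble(particle = seq_along(x$heights), height_nm = x$heights)
}
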