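#' Feature descriptors for synthetic AFM topographs
#'
#' Helpers building the `features` tibble consumed by
#' [sim_topograph()]. Positions and lateral sizes are in nm, heights in
#' nm. Three aggregate morphologies are rendered:
#' * `topo_cap()` — a spherical cap (globular aggregate) of apex
#'   height `height` and base radius `radius`;
#' * `topo_disk()` — a flat-topped plateau of height `height` and
#'   radius `radius` (disk-shaped aggregate);
#' * `topo_fibril()` — a half-cylindrical ridge between two endpoints,
#'   apex height `height` and full lateral width `width` (the width is
#'   treated as the tip-convolved apparent width, independent of the
#'   apex height).
#'
#' @param x,y Centre position in nm.
#' @param height Apex/plateau height in nm (>= 0).
#' @param radius Base radius in nm.
#' @param x1,y1,x2,y2 Fibril endpoints in nm.
#' @param width Fibril full width in nm.
#' @return One-row tibble describing the feature.
#' @name topo_features
NULL

#' @rdname topo_features
#' @export
topo_cap <- function(x, y, height, radius) {
  tibble(shape = "cap", x = x, y = y, x2 = NA_real_, y2 = NA_real_,
         height = height, size = radius)
}

#' @rdname topo_features
#' @export
topo_disk <- function(x, y, height, radius) {
  tibble(shape = "disk", x = x, y = y, x2 = NA_real_, y2 = NA_real_,
         height = height, size = radius)
}

#' @rdname topo_features
#' @export
topo_fibril <- function(x1, y1, x2, y2, height, width) {
  tibble(shape = "fibril", x = x1, y = y1, x2 = x2, y2 = y2,
         height = height, size = width)
}

#' Simulate an AFM topograph
#'
#' Renders a height map from a list of surface features plus Gaussian
#' roughness. Overlapping features compose by the pointwise maximum
#' (an AFM tip reads the tallest surface), never by summation.
#' A spherical cap of apex height \eqn{h} and base radius \eqn{a} has
#' profile \eqn{z(r) = \sqrt{R_s^2 - r^2} - (R_s - h)} with sphere
#' radius \eqn{R_s = (a^2 + h^2)/(2h)}; a disk is a flat plateau; a
#' fibril is a ridge with half-elliptical cross-section (apex equal to
#' the stated height).
#'
#' @param features Tibble of features from [topo_cap()] /
#'   [topo_disk()] / [topo_fibril()] rows (bind with
#'   [dplyr::bind_rows()]); may have zero rows. All features must fit
#'   inside the grid and have non-negative heights.
#' @param grid_px Grid side length in pixels (square map).
#' @param pixel_nm Pixel size in nm.
#' @param roughness_sd Gaussian surface roughness SD in nm.
#' @param seed Integer seed (used for the roughness only).
#' @return Object of class `topograph`: list with `heights`
#'   (`grid_px` x `grid_px` matrix, nm), `pixel_nm`, `features`, `id`.
#' @export
#' @examples
#' topo <- sim_topograph(topo_cap(50, 50, 2.65, 10),
#'                       grid_px = 100, pixel_nm = 1, roughness_sd = 0)
#' max(topo$heights)
sim_topograph <- function(features = NULL, grid_px = 256, pixel_nm = 2,
                          roughness_sd = 0.05, seed = 1) {
  stopifnot(grid_px >= 2, pixel_nm > 0, roughness_sd >= 0)
  if (is.null(features)) {
    features <- tibble(shape = character(), x = numeric(), y = numeric(),
                       x2 = numeric(), y2 = numeric(), height = numeric(),
                       size = numeric())
  }
  if (nrow(features) > 0) {
    if (any(features$height < 0)) {
      abort("feature heights must be >= 0.", class = "smc_param_error")
    }
    extent <- grid_px * pixel_nm
    xs <- c(features$x, features$x2[!is.na(features$x2)])
    ys <- c(features$y, features$y2[!is.na(features$y2)])
    if (any(xs < 0 | xs > extent | ys < 0 | ys > extent)) {
      abort("all features must lie inside the grid.",
            class = "smc_param_error")
    }
  }
  set.seed(seed)
  # pixel-centre coordinates in nm: pixel (i, j) is at ((i-0.5), (j-0.5)) * pixel_nm
  cx <- (seq_len(grid_px) - 0.5) * pixel_nm
  xmat <- matrix(cx, grid_px, grid_px)
  ymat <- matrix(cx, grid_px, grid_px, byrow = TRUE)
  z <- matrix(0, grid_px, grid_px)

  for (i in seq_len(nrow(features))) {
    ft <- features[i, ]
    if (ft$shape == "cap") {
      r2 <- (xmat - ft$x)^2 + (ymat - ft$y)^2
      rs <- (ft$size^2 + ft$height^2) / (2 * ft$height)
      zi <- sqrt(pmax(rs^2 - r2, 0)) - (rs - ft$height)
      zi[r2 > ft$size^2] <- 0
    } else if (ft$shape == "disk") {
      r2 <- (xmat - ft$x)^2 + (ymat - ft$y)^2
      zi <- ifelse(r2 <= ft$size^2, ft$height, 0)
    } else if (ft$shape == "fibril") {
      # distance from the segment (x, y) -- (x2, y2)
      vx <- ft$x2 - ft$x; vy <- ft$y2 - ft$y
      len2 <- vx^2 + vy^2
      t <- pmin(pmax(((xmat - ft$x) * vx + (ymat - ft$y) * vy) / len2, 0), 1)
      d2 <- (xmat - (ft$x + t * vx))^2 + (ymat - (ft$y + t * vy))^2
      half_w <- ft$size / 2
      zi <- ft$height * sqrt(pmax(1 - d2 / half_w^2, 0))
    } else {
      abort(paste0("unknown feature shape: ", ft$shape),
            class = "smc_param_error")
    }
    z <- pmax(z, zi)
  }
  if (roughness_sd > 0) {
    z <- z + matrix(rnorm(grid_px^2, 0, roughness_sd), grid_px, grid_px)
  }
  structure(list(heights = z, pixel_nm = pixel_nm, features = features,
                 id = sprintf("topo_seed%d", seed)),
            class = "topograph")
}

#' @export
print.topograph <- function(x, ...) {
  cat(sprintf("AFM topograph: %d x %d px at %.2g nm/px, height range [%.2f, %.2f] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_nm,
              min(x$heights), max(x$heights)))
  invisible(x)
}
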