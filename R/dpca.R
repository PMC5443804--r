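#' Circular sin/cos featurisation of a dihedral trajectory
#'
#' Maps each kept dihedral angle \eqn{\theta} to the pair
#' \eqn{(\cos\theta, \sin\theta)}, the standard transformation that
#' removes the \eqn{\pm 180^\circ} periodicity before principal
#' component analysis (dihedral PCA). Angles of the terminal residues
#' are excluded via the trajectory's `terminal_mask`: chain ends are
#' conformationally floppy and would dominate the variance.
#'
#' @param traj A `dihedral_traj` object ([sim_dihedral_traj()] or
#'   [read_dihedral_traj()]), or a frames x angles matrix of degrees
#'   (then `terminal_mask` applies if supplied).
#' @param terminal_mask Optional logical per-column mask of angles to
#'   drop (overrides the trajectory's own mask).
#' @return A frames x (2 * n_kept) numeric matrix with columns
#'   `cos_<k>`, `sin_<k>` interleaved.
#' @export
dihedral_features <- function(traj, terminal_mask = NULL) {
  if (inherits(traj, "dihedral_traj")) {
    ang <- traj$angles
    mask <- terminal_mask %||% traj$terminal_mask
  } else {
    ang <- as.matrix(traj)
    mask <- terminal_mask %||% rep(FALSE, ncol(ang))
  }
  if (nrow(ang) < 2) abort("need >= 2 frames.", class = "smc_param_error")
  keep <- which(!mask)
  if (length(keep) == 0) {
    abort("terminal mask excludes every angle.", class = "smc_param_error")
  }
  rad <- ang[, keep, drop = FALSE] * pi / 180
  out <- matrix(NA_real_, nrow(rad), 2L * ncol(rad))
  out[, seq(1, ncol(out), by = 2)] <- cos(rad)
  out[, seq(2, ncol(out), by = 2)] <- sin(rad)
  colnames(out) <- paste0(rep(c("cos_", "sin_"), length(keep)),
                          rep(keep, each = 2))
  out
}

#' Project features onto the top two principal components
#'
#' Mean-centred covariance eigendecomposition of the sin/cos feature
#' matrix; frames are projected on the two largest-eigenvalue
#' directions V1 and V2. The sign of each component is fixed by making
#' its largest-magnitude loading positive, so projections are
#' deterministic.
#'
#' @param features Frames x features numeric matrix from
#'   [dihedral_features()].
#' @return Object of class `dpca_projection`: list with `scores`
#'   (tibble `V1`, `V2`), `explained` (fraction of variance of each of
#'   the top two components), `eigenvalues` (all, descending),
#'   `loadings` (features x 2).
#' @export
dpca_project <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3) abort("need >= 3 frames.", class = "smc_param_error")
  if (all(apply(features, 2, sd) < 1e-12)) {
    abort("zero variance: all frames identical.", class = "smc_param_error")
  }
  pc <- prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  load <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(
    list(scores = tibble(V1 = pc$x[, 1], V2 = pc$x[, 2]),
         explained = ev[1:2] / sum(ev),
         eigenvalues = ev, loadings = load),
    class = "dpca_projection")
}

#' @export
print.dpca_projection <- function(x, ...) {
  cat(sprintf(
    "dPCA projection: %d frames; V1 %.1f%%, V2 %.1f%% of variance\n",
    nrow(x$scores), 100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' @rdname dpca_project
#' @param x A `dpca_projection` object.
#' @param ... Unused.
#' @export
glance.dpca_projection <- function(x, ...) {
  tibble(n_frames = nrow(x$scores),
         var_V1 = x$explained[1], var_V2 = x$explained[2])
}

#' @rdname dpca_project
#' @export
tidy.dpca_projection <- function(x, ...) {
  x$scores
}

#' Free-energy surface over the principal components
#'
#' Bins the (V1, V2) projections into a 2-D histogram and converts the
#' occupancy P to a free energy in units of \eqn{k_B T},
#' \deqn{\Delta G(V_1, V_2) = -k_B T \ln\frac{P(V_1, V_2)}{P_{max}},}
#' where \eqn{P_{max}} is the histogram maximum, so the most populated
#' bin sits at \eqn{\Delta G = 0} and every populated bin is
#' non-negative. Empty bins hold `NA` (an honest sentinel, not an
#' arbitrary cap, so minima searches cannot wander into unsampled
#' territory). The grid covers the data range padded by 5% on each
#' side.
#'
#' @param projection A `dpca_projection` object, or a data frame with
#'   `V1`, `V2` columns.
#' @param bins Number of bins per axis (default 50).
#' @return Object of class `fep_grid`: list with `deltaG` (bins x bins
#'   matrix, kBT), `v1_edges`, `v2_edges`, `pmax_bin` (row, col index
#'   of the global minimum), `counts`, `n_frames`.
#' @export
free_energy_surface <- function(projection, bins = 50) {
  sc <- if (inherits(projection, "dpca_projection")) projection$scores
        else as_tibble(projection)
  stopifnot(all(c("V1", "V2") %in% names(sc)), bins >= 2)
  v1 <- sc$V1; v2 <- sc$V2
  n <- length(v1)
  if (n < 100) {
    warn("fewer than 100 frames: the landscape will be noisy.")
  }
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1e-6)
    r + c(-0.05, 0.05) * w
  }
  r1 <- pad(range(v1)); r2 <- pad(range(v2))
  e1 <- seq(r1[1], r1[2], length.out = bins + 1)
  e2 <- seq(r2[1], r2[2], length.out = bins + 1)
  i1 <- pmin(pmax(findInterval(v1, e1, rightmost.closed = TRUE), 1L), bins)
  i2 <- pmin(pmax(findInterval(v2, e2, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (k in seq_len(n)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1L
  if (sum(counts > 0) == 1) {
    warn("degenerate landscape: all frames fall in a single bin.")
  }
  pmax_val <- max(counts)
  dG <- matrix(NA_real_, bins, bins)
  pop <- counts > 0
  dG[pop] <- -log(counts[pop] / pmax_val)
  pmax_bin <- which(counts == pmax_val, arr.ind = TRUE)[1, ]
  structure(list(deltaG = dG, v1_edges = e1, v2_edges = e2,
                 pmax_bin = unname(pmax_bin), counts = counts, n_frames = n),
            class = "fep_grid")
}

#' @export
print.fep_grid <- function(x, ...) {
  cat(sprintf(
    "Free-energy surface: %d x %d bins, %d frames, max dG %.2f kBT (%d empty bins)\n",
    nrow(x$deltaG), ncol(x$deltaG), x$n_frames,
    max(x$deltaG, na.rm = TRUE), sum(is.na(x$deltaG))))
  invisible(x)
}

#' @rdname free_energy_surface
#' @param x An `fep_grid` object.
#' @param ... Unused.
#' @export
tidy.fep_grid <- function(x, ...) {
  m1 <- (x$v1_edges[-1] + x$v1_edges[-length(x$v1_edges)]) / 2
  m2 <- (x$v2_edges[-1] + x$v2_edges[-length(x$v2_edges)]) / 2
  tibble(V1 = rep(m1, times = length(m2)),
         V2 = rep(m2, each = length(m1)),
         deltaG = as.vector(x$deltaG),
         count = as.vector(x$counts))
}

#' Locate conformational minima on a free-energy surface
#'
#' Finds the basins of the landscape by a watershed-style merge pass:
#' populated bins are visited in order of increasing \eqn{\Delta G},
#' each local minimum (8-neighbourhood) seeds a basin, and when a
#' shallower basin first meets a deeper one their saddle height
#' \eqn{s} decides its fate -- it is a genuine conformational minimum
#' only if its depth below the saddle, \eqn{s - \Delta G_{min}}, is at
#' least `depth_threshold` (persistence criterion), so noise basins
#' merge away. Because a finite-sample histogram puts Poisson noise of
#' order \eqn{\ln 2} between one- and two-count fringe bins, the
#' barrier must also clear its own counting uncertainty: the log count
#' ratio carries standard error \eqn{\sqrt{1/c_{seed} + 1/c_{saddle}}}
#' (delta method), and confirmation requires the barrier to exceed
#' `depth_threshold` by `sig_z` of these standard errors. The seeding
#' bin must additionally hold at least `min_count` frames. Basins that
#' never meet another basin
#' (states disconnected across unsampled territory, and the global
#' basin itself) are kept when the landscape relief (highest populated
#' level) reaches the threshold and their total population reaches
#' `min_population` frames; a uniform-occupancy landscape therefore
#' yields no minima while any structured landscape reports its global
#' minimum at \eqn{\Delta G = 0}.
#'
#' @param fep An `fep_grid` object.
#' @param depth_threshold Minimum basin depth in kBT (default 0.5).
#' @param min_count Minimum frame count of a seeding bin.
#' @param min_population Minimum total frame count of a basin that
#'   never merges (isolated states).
#' @param sig_z Significance multiplier on the Poisson standard error
#'   of the barrier height.
#' @return Tibble of minima sorted by `deltaG`: `row`, `col`, `V1`,
#'   `V2` (bin centres), `deltaG`, `persistence` (saddle height above
#'   the minimum; landscape relief for the global basin), and
#'   `population` (total frame count of bins draining into the basin,
#'   see [basin_free_energies()]).
#' @seealso [basin_free_energies()] for occupancy-integrated basin
#'   free energies.
#' @export
find_minima <- function(fep, depth_threshold = 0.5, min_count = 5,
                        min_population = 50, sig_z = 3) {
  stopifnot(inherits(fep, "fep_grid"))
  ws <- fep_watershed(fep, depth_threshold, min_count, min_population, sig_z)
  keep <- ws$confirmed
  empty <- tibble(row = integer(), col = integer(), V1 = numeric(),
                  V2 = numeric(), deltaG = numeric(),
                  persistence = numeric(), population = numeric())
  if (length(keep) == 0) return(empty)
  dG <- fep$deltaG
  nb <- nrow(dG)
  m1 <- (fep$v1_edges[-1] + fep$v1_edges[-length(fep$v1_edges)]) / 2
  m2 <- (fep$v2_edges[-1] + fep$v2_edges[-length(fep$v2_edges)]) / 2
  rows <- ((keep - 1L) %% nb) + 1L
  cols <- ((keep - 1L) %/% nb) + 1L
  tibble(row = rows, col = cols, V1 = m1[rows], V2 = m2[cols],
         deltaG = dG[keep], persistence = ws$persistence[as.character(keep)],
         population = ws$population[as.character(keep)]) |>
    arrange(.data$deltaG)
}

# watershed merge pass shared by find_minima() and basin_free_energies():
# returns confirmed minima (bin indices), their persistence, and the
# total histogram count draining into each confirmed basin
fep_watershed <- function(fep, depth_threshold, min_count = 5,
                          min_population = 50, sig_z = 3) {
  dG <- fep$deltaG
  counts <- fep$counts
  nb <- nrow(dG); nc <- ncol(dG)
  pop <- which(!is.na(dG))
  ord <- pop[order(dG[pop])]
  parent <- integer(nb * nc)         # union-find; 0 = untouched
  base <- rep(NA_real_, nb * nc)     # basin minimum value at root
  seed_of <- integer(nb * nc)        # seeding bin of the root
  confirmed <- integer(0)
  persistence <- numeric(0)
  drain <- integer(nb * nc)          # seed bin each visited bin drains to
  merged_into <- integer(nb * nc)    # absorber seed recorded at merge time
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (idx in ord) {
    r <- ((idx - 1L) %% nb) + 1L
    cc <- ((idx - 1L) %/% nb) + 1L
    nbrs <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > nb || c2 < 1 || c2 > nc) next
      j <- (c2 - 1L) * nb + rr
      if (parent[j] != 0L) nbrs <- c(nbrs, find_root(j))
    }
    nbrs <- unique(nbrs)
    if (length(nbrs) == 0) {
      parent[idx] <- idx
      base[idx] <- dG[idx]
      seed_of[idx] <- idx
      drain[idx] <- idx
    } else {
      deep <- nbrs[which.min(base[nbrs])]
      parent[idx] <- deep
      drain[idx] <- seed_of[deep]
      for (other in setdiff(nbrs, deep)) {
        # the two basins meet here: saddle at the current level
        barrier <- dG[idx] - base[other]
        seed <- seed_of[other]
        need <- depth_threshold +
          sig_z * sqrt(1 / counts[seed] + 1 / counts[idx])
        if (barrier >= need && counts[seed] >= min_count &&
            !(seed %in% confirmed)) {
          confirmed <- c(confirmed, seed)
          persistence <- c(persistence, barrier)
        }
        merged_into[seed] <- seed_of[deep]
        parent[other] <- deep
      }
    }
  }
  # basins that never met another basin: the global basin and any state
  # disconnected across unsampled bins; kept when the landscape has
  # relief. Border bins are excluded from the relief: the 5% range
  # padding dilutes them geometrically, which is binning artefact, not
  # occupancy structure (a uniform distribution must yield no minima).
  interior <- matrix(FALSE, nb, nc)
  interior[2:(nb - 1), 2:(nc - 1)] <- TRUE
  rel_bins <- which(!is.na(dG) & interior)
  relief <- if (length(rel_bins)) max(dG[rel_bins]) else 0
  roots <- unique(vapply(which(parent != 0L), find_root, integer(1)))
  if (relief >= depth_threshold) {
    for (rt in roots) {
      seed <- seed_of[rt]
      if (counts[seed] >= min_count && !(seed %in% confirmed)) {
        confirmed <- c(confirmed, seed)
        persistence <- c(persistence, relief - base[rt])
      }
    }
  }
  names(persistence) <- as.character(confirmed)
  # resolve each bin's drain label: unconfirmed noise seeds hand their
  # bins to whichever basin absorbed them; confirmed seeds keep theirs
  resolve <- function(s) {
    while (!(s %in% confirmed) && merged_into[s] != 0L) s <- merged_into[s]
    s
  }
  seeds <- unique(drain[drain != 0L])
  resolved <- vapply(seeds, resolve, integer(1))
  map <- stats::setNames(resolved, as.character(seeds))
  final_seed <- integer(nb * nc)
  vis <- which(drain != 0L)
  final_seed[vis] <- map[as.character(drain[vis])]
  population <- vapply(confirmed, function(s)
    sum(counts[final_seed == s]), numeric(1))
  names(population) <- as.character(confirmed)
  # never-merged basins must carry real statistical weight
  isolated <- confirmed[merged_into[confirmed] == 0L]
  weak <- isolated[population[as.character(isolated)] < min_population &
                   isolated != seed_of[find_root(ord[1])]]
  keep <- setdiff(confirmed, weak)
  list(confirmed = keep,
       persistence = persistence[as.character(keep)],
       population = population[as.character(keep)])
}

#' Occupancy-integrated basin free energies
#'
#' Complements the per-bin minima of [find_minima()]: each populated
#' bin is assigned to the confirmed basin it drains into, basin
#' occupancies are summed, and free energies are reported as
#' \eqn{\Delta G_i = -\ln(P_i / P_{max})} over basin populations. For
#' well-separated states this estimator recovers
#' \eqn{-\ln(p_i / p_j)} of the underlying state occupancies with
#' plain multinomial error, unaffected by bin-width and peak-alignment
#' noise of single-bin estimates.
#'
#' @inheritParams find_minima
#' @return Tibble sorted by `deltaG`: `row`, `col` (basin minimum
#'   bin), `population`, `occupancy`, `deltaG`.
#' @export
basin_free_energies <- function(fep, depth_threshold = 0.5, min_count = 5,
                                min_population = 50, sig_z = 3) {
  stopifnot(inherits(fep, "fep_grid"))
  ws <- fep_watershed(fep, depth_threshold, min_count, min_population, sig_z)
  if (length(ws$confirmed) == 0) {
    return(tibble(row = integer(), col = integer(), population = numeric(),
                  occupancy = numeric(), deltaG = numeric()))
  }
  nb <- nrow(fep$deltaG)
  popn <- ws$population
  tibble(row = ((ws$confirmed - 1L) %% nb) + 1L,
         col = ((ws$confirmed - 1L) %/% nb) + 1L,
         population = unname(popn),
         occupancy = unname(popn) / sum(fep$counts),
         deltaG = -log(unname(popn) / max(popn))) |>
    arrange(.data$deltaG)
}
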