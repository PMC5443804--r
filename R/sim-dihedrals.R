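#' Simulate a multi-state backbone dihedral trajectory
#'
#' Draws frames from a mixture of conformational states. Each state is
#' a set of centre angles (one phi and one psi per residue) with von
#' Mises scatter of common concentration `kappa`; frames are assigned
#' to states by the stated occupancies. This provides trajectories with
#' known state populations for validating the dihedral-PCA free-energy
#' landscape machinery.
#'
#' @param states A list of states, each a list with `centers` (numeric
#'   vector of angles in degrees, length `2 * n_residues`, order phi1,
#'   psi1, phi2, psi2, ...; values in (-180, 180]), `kappa` (von Mises
#'   concentration, >= 0; 0 gives uniform scatter, large values tight
#'   scatter) and `occupancy`. Occupancies must sum to 1.
#' @param n_frames Number of frames.
#' @param n_residues Number of residues; the first and last residue are
#'   marked terminal (their angles are conventionally ignored by the
#'   analysis).
#' @param seed Integer seed.
#' @return Object of class `dihedral_traj`: list with `angles`
#'   (`n_frames` x `2 * n_residues` matrix, degrees in (-180, 180]),
#'   `labels` (tibble `residue`, `angle`), `terminal_mask` (logical per
#'   column), `state` (true state index per frame).
#' @export
#' @examples
#' st <- list(list(centers = rep(c(-60, -45), 5), kappa = 20, occupancy = 0.8),
#'            list(centers = rep(c(-120, 130), 5), kappa = 20, occupancy = 0.2))
#' traj <- sim_dihedral_traj(st, n_frames = 1000, n_residues = 5, seed = 1)
#' table(traj$state) / 1000
sim_dihedral_traj <- function(states, n_frames, n_residues, seed = 1) {
  stopifnot(n_frames >= 1, n_residues >= 2)
  occ <- map_dbl(states, "occupancy")
  if (abs(sum(occ) - 1) > 1e-8) {
    abort("state occupancies must sum to 1.", class = "smc_param_error")
  }
  n_ang <- 2L * n_residues
  for (s in states) {
    if (length(s$centers) != n_ang) {
      abort("each state needs 2 * n_residues centre angles.",
            class = "smc_param_error")
    }
    if (any(s$centers <= -180 | s$centers > 180)) {
      abort("centre angles must lie in (-180, 180].",
            class = "smc_param_error")
    }
  }
  set.seed(seed)
  state <- sample.int(length(states), n_frames, replace = TRUE, prob = occ)
  angles <- matrix(NA_real_, n_frames, n_ang)
  for (k in seq_along(states)) {
    idx <- which(state == k)
    if (length(idx) == 0) next
    kap <- states[[k]]$kappa
    ctr <- states[[k]]$centers * pi / 180
    for (a in seq_len(n_ang)) {
      th <- if (kap == 0) runif(length(idx), -pi, pi)
            else rvonmises(length(idx), ctr[a], kap)
      angles[idx, a] <- th * 180 / pi
    }
  }
  # wrap into (-180, 180]
  angles <- ((angles + 180) %% 360) - 180
  angles[angles == -180] <- 180

  labels <- tibble(residue = rep(seq_len(n_residues), each = 2),
                   angle = rep(c("phi", "psi"), n_residues))
  terminal_mask <- labels$residue %in% c(1L, n_residues)
  structure(list(angles = angles, labels = labels,
                 terminal_mask = terminal_mask, state = state),
            class = "dihedral_traj")
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa > 0
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

#' @export
print.dihedral_traj <- function(x, ...) {
  cat(sprintf("Dihedral trajectory: %d frames x %d angles (%d terminal columns masked)\n",
              nrow(x$angles), ncol(x$angles), sum(x$terminal_mask)))
  invisible(x)
}
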