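#' Go-model energy of a coarse-grained configuration
#'
#' Total potential energy in kBT units: harmonic bonds, 12-10
#' native-contact wells (each contributes exactly `-depth` at its rest
#' length; the salt-bridge class carries double depth via its `depth`
#' entry), and truncated soft-sphere repulsion between non-bonded,
#' non-contact bead pairs. Overlapping beads give a large but always
#' finite energy (inter-bead distances are clamped away from zero).
#'
#' @param model A `cg_model` from [cg_dimer()].
#' @param coords Optional n x 3 coordinate matrix (defaults to the
#'   model's native coordinates, for which the bond terms vanish and
#'   the energy equals minus the summed contact depths).
#' @param eps_rep Repulsion strength in kBT.
#' @return Energy in kBT (scalar).
#' @export
#' @examples
#' hm <- cg_dimer("HM")
#' cg_energy(hm)  # -sum(hm$contacts$depth)
cg_energy <- function(model, coords = NULL, eps_rep = 1) {
  stopifnot(inherits(model, "cg_model"))
  coords <- coords %||% model$coords
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(model$coords), ncol(coords) == 3,
            all(is.finite(coords)))
  cg_energy_cpp(coords, as.data.frame(model$bonds),
                contacts_df(model), model$sigma_rep, eps_rep)
}

contacts_df <- function(model) {
  cx <- as.data.frame(model$contacts)
  cx$inter <- cx$class != "intra"
  cx
}

#' Monte Carlo pulling of a coarse-grained dimer
#'
#' Metropolis dynamics with two virtual springs. A spring is attached
#' to each pulling-group bead and its anchor recedes along the pulling
#' vector at `velocity` nm per sweep (total separation
#' rate), mimicking a constant-velocity retraction. One sweep attempts
#' one single-bead Gaussian displacement per bead. The spring force
#' (pN) is recorded every sweep; the run ends at the rupture sweep --
#' the first sweep at which the fraction of formed inter-chain
#' contacts (pair distance < 1.5 rest length) falls below
#' `contact_break_fraction` -- or when the sweep budget is exhausted.
#' The rupture force is the maximum spring force seen before rupture.
#'
#' The spring stiffness, move step, and rupture criterion are model
#' choices of this simulator (defaults: 25 pN/nm within the
#' experimental cantilever range, 0.05 nm steps giving roughly 40-60%
#' acceptance, break fraction 0.25). The velocity is in nm per sweep;
#' it is not convertible to the instrument nm/s without a physical
#' time per sweep.
#'
#' @param model A `cg_model`.
#' @param k_spring Virtual-spring stiffness in pN/nm.
#' @param velocity Anchor separation rate in nm/sweep.
#' @param temperature Temperature in K.
#' @param sweeps Production sweep budget.
#' @param step Trial-move SD in nm.
#' @param contact_break_fraction Rupture threshold on the formed
#'   inter-contact fraction, in (0, 1).
#' @param equil_sweeps Equilibration sweeps with static anchors before
#'   pulling starts.
#' @param seed Integer seed.
#' @param axis Length-3 pulling vector (normalised internally).
#'   Defaults to the model's `pulling_axis` when present, otherwise to
#'   the initial vector between the two pulling-group beads.
#' @param eps_rep Repulsion strength in kBT.
#' @param record_group_coords Also record the group-a bead coordinates
#'   every sweep (used for sampling diagnostics).
#' @param stop_at_rupture Stop the run at the rupture sweep (default).
#'   Set `FALSE` for equilibrium sampling runs (e.g. `velocity = 0`
#'   diagnostics), where the trace continues for the full sweep budget.
#' @return Object of class `pulling_trace`: list with `trace` (tibble
#'   `sweep`, `separation`, `force`, `inter_fraction`),
#'   `rupture_force` (pN), `rupture_sweep` (NA if never ruptured),
#'   `acceptance`, `config`, and optionally `group_coords`.
#' @export
#' @examples
#' tr <- mc_pull(cg_dimer("HM"), sweeps = 500, seed = 1)
#' tr$acceptance
mc_pull <- function(model, k_spring = 25, velocity = 0.002,
                    temperature = 298, sweeps = 30000, step = 0.05,
                    contact_break_fraction = 0.25, equil_sweeps = 200,
                    seed = 1, axis = NULL, eps_rep = 1,
                    record_group_coords = FALSE, stop_at_rupture = TRUE) {
  stopifnot(inherits(model, "cg_model"))
  if (k_spring <= 0 || velocity < 0 || step <= 0 || sweeps < 1) {
    abort("k_spring, step must be > 0; velocity >= 0; sweeps >= 1.",
          class = "smc_param_error")
  }
  if (contact_break_fraction <= 0 || contact_break_fraction >= 1) {
    abort("contact_break_fraction must lie in (0, 1).",
          class = "smc_param_error")
  }
  axis <- axis %||% model$pulling_axis %||% numeric(0)
  set.seed(seed)
  res <- mc_pull_cpp(model$coords, as.data.frame(model$bonds),
                     contacts_df(model), model$sigma_rep, eps_rep,
                     model$pulling_groups[1], model$pulling_groups[2],
                     k_spring, kBT(temperature), velocity,
                     as.integer(sweeps), step, contact_break_fraction,
                     as.integer(equil_sweeps), record_group_coords,
                     as.numeric(axis), stop_at_rupture)
  out <- list(
    trace = tibble(sweep = res$sweep, separation = res$separation,
                   force = res$force, inter_fraction = res$inter_fraction),
    rupture_force = res$rupture_force,
    rupture_sweep = if (is.na(res$rupture_sweep)) NA_integer_
                    else res$rupture_sweep,
    acceptance = res$acceptance,
    final_coords = res$final_coords,
    config = list(kind = model$kind, k_spring = k_spring,
                  velocity = velocity, temperature = temperature,
                  sweeps = sweeps, step = step,
                  contact_break_fraction = contact_break_fraction,
                  seed = seed))
  if (record_group_coords) out$group_coords <- as_tibble(res$group_coords)
  structure(out, class = "pulling_trace")
}

#' @export
print.pulling_trace <- function(x, ...) {
  rup <- if (is.na(x$rupture_sweep)) "no rupture within budget"
         else sprintf("rupture at sweep %d", x$rupture_sweep)
  cat(sprintf("MC pulling (%s): rupture force %.1f pN, %s, acceptance %.0f%%\n",
              x$config$kind, x$rupture_force, rup, 100 * x$acceptance))
  invisible(x)
}

#' @rdname mc_pull
#' @param x A `pulling_trace` object.
#' @param ... Unused.
#' @export
tidy.pulling_trace <- function(x, ...) {
  x$trace
}

#' @rdname mc_pull
#' @export
glance.pulling_trace <- function(x, ...) {
  tibble(kind = x$config$kind, rupture_force = x$rupture_force,
         rupture_sweep = x$rupture_sweep, acceptance = x$acceptance,
         n_sweeps = nrow(x$trace))
}

#' Repeat-pull a model over many seeds
#'
#' Runs [mc_pull()] once per seed and collects per-run rupture
#' statistics, the analogue of repeating the pulling experiment.
#'
#' @param model A `cg_model`.
#' @param seeds Integer vector of seeds (one run each).
#' @param ... Passed to [mc_pull()].
#' @return Tibble with `seed`, `rupture_force`, `rupture_sweep`,
#'   `acceptance`.
#' @export
pull_batch <- function(model, seeds = 1:50, ...) {
  purrr::map(seeds, function(s) {
    tr <- mc_pull(model, seed = s, ...)
    tibble(seed = s, rupture_force = tr$rupture_force,
           rupture_sweep = tr$rupture_sweep, acceptance = tr$acceptance)
  }) |> bind_rows()
}

#' Rupture-force statistics over pulling runs
#'
#' Mean and sample SD of per-trace rupture forces.
#'
#' @param traces A list of `pulling_trace` objects, a tibble from
#'   [pull_batch()], or a numeric vector of rupture forces. At least 2.
#' @return Tibble with `mean`, `sd`, `n`.
#' @export
rupture_stats <- function(traces) {
  forces <- if (is.numeric(traces)) {
    traces
  } else if (is.data.frame(traces)) {
    traces$rupture_force
  } else {
    map_dbl(traces, function(t) t$rupture_force)
  }
  if (length(forces) < 2) {
    abort("need >= 2 pulling traces.", class = "smc_param_error")
  }
  tibble(mean = mean(forces), sd = sd(forces), n = length(forces))
}
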