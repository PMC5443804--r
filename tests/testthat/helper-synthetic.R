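# shared fixture builders (all synthetic, generated at test time)

# regular field of n non-overlapping cap/disk features with heights drawn
# Normal(mean_h, sd_h) truncated at 0.2 nm; features sit on pixel centres
feature_field <- function(shape = c("cap", "disk"), n = 100,
                          mean_h = 2.65, sd_h = 0.61, radius = 8,
                          cell = 32, seed = 1) {
  shape <- match.arg(shape)
  set.seed(seed)
  heights <- pmax(rnorm(n, mean_h, sd_h), 0.2)
  side <- ceiling(sqrt(n))
  pos <- expand.grid(i = seq_len(side) - 1, j = seq_len(side) - 1)[seq_len(n), ]
  make <- if (shape == "cap") topo_cap else topo_disk
  feats <- dplyr::bind_rows(lapply(seq_len(n), function(k) {
    make(pos$i[k] * cell + cell / 2 + 0.5,
         pos$j[k] * cell + cell / 2 + 0.5, heights[k], radius)
  }))
  list(features = feats, heights = heights, grid_px = side * cell)
}

# two-bead toy (two one-bead chains far apart): each bead is an
# independent particle on its virtual spring
two_bead_toy <- function(separation = 5) {
  cg_model(coords = rbind(c(0, 0, 0), c(separation, 0, 0)),
           chain = c(1, 2), pulling_groups = c(1, 2))
}

# two-state dihedral mixture with equal, broad scatter
two_state_traj <- function(n_frames, occ = c(0.8, 0.2), kappa = 10,
                           n_residues = 6, seed = 1) {
  states <- list(
    list(centers = rep(c(-60, -45), n_residues), kappa = kappa,
         occupancy = occ[1]),
    list(centers = rep(c(-120, 130), n_residues), kappa = kappa,
         occupancy = occ[2]))
  sim_dihedral_traj(states, n_frames = n_frames, n_residues = n_residues,
                    seed = seed)
}
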