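test_that("sin/cos featurisation maps angles correctly and drops termini", {
  ang <- matrix(c(0, 90, 180, -90), nrow = 2, ncol = 4, byrow = TRUE)
  ft <- dihedral_features(ang)
  expect_equal(ft[1, 1:2], c(cos_1 = 1, sin_1 = 0))
  expect_equal(ft[1, 3:4], c(cos_2 = 0, sin_2 = 1), tolerance = 1e-12)

  traj <- two_state_traj(50, n_residues = 6, seed = 61)
  ft2 <- dihedral_features(traj)
  # 6 residues, terminal two excluded: 4 residues x 2 angles x (cos, sin)
  expect_identical(ncol(ft2), 16L)
  expect_error(dihedral_features(ang, terminal_mask = rep(TRUE, 4)),
               class = "smc_param_error")
})

test_that("projection finds the dominant direction deterministically", {
  # perfectly collinear features: first component explains everything
  set.seed(62)
  t <- rnorm(200)
  line <- cbind(t, 2 * t, -t)
  pr <- dpca_project(line)
  expect_equal(pr$explained[1], 1, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive
  expect_gt(pr$loadings[which.max(abs(pr$loadings[, 1])), 1], 0)

  # isotropic 2-D cloud: eigenvalues equal within sampling error
  iso <- matrix(rnorm(40000), ncol = 2)
  pr2 <- dpca_project(iso)
  expect_lt(abs(pr2$eigenvalues[1] / pr2$eigenvalues[2] - 1), 0.1)

  expect_error(dpca_project(matrix(1, 50, 4)), class = "smc_param_error")
})

test_that("free-energy surface obeys the Boltzmann inversion identities", {
  traj <- two_state_traj(5000, seed = 63)
  fep <- free_energy_surface(dpca_project(dihedral_features(traj)))
  dG <- fep$deltaG
  # Pmax bin sits at exactly zero; populated bins are non-negative
  expect_identical(dG[fep$pmax_bin[1], fep$pmax_bin[2]], 0)
  expect_true(all(dG[!is.na(dG)] >= 0))
  # empty bins are sentinels, not capped numbers
  expect_true(anyNA(dG))

  # doubling all counts leaves the landscape unchanged
  fep2 <- fep
  fep2$counts <- fep$counts * 2L
  pop <- fep$counts > 0
  dG2 <- matrix(NA_real_, nrow(dG), ncol(dG))
  dG2[pop] <- -log(fep2$counts[pop] / max(fep2$counts))
  expect_equal(dG2, dG)

  # permutation invariance over frames
  pr <- dpca_project(dihedral_features(traj))
  set.seed(64)
  perm <- sample(nrow(pr$scores))
  fep_p <- free_energy_surface(pr$scores[perm, ])
  expect_equal(fep_p$deltaG, fep$deltaG)
})

test_that("two-state occupancies produce the analytic free-energy gap", {
  traj <- two_state_traj(50000, occ = c(0.8, 0.2), seed = 65)
  fep <- free_energy_surface(dpca_project(dihedral_features(traj)))
  mins <- find_minima(fep, depth_threshold = 0.5)
  expect_identical(nrow(mins), 2L)
  expect_identical(mins$deltaG[1], 0)
  # Delta G gap = -ln(p2/p1) = ln 4
  expect_lt(abs((mins$deltaG[2] - mins$deltaG[1]) - log(4)), 0.1)
})

test_that("minima search reports structure only where it exists", {
  # three states: all pairwise gaps match the occupancy ratios
  states <- list(
    list(centers = rep(c(-60, -45), 6), kappa = 10, occupancy = 0.6),
    list(centers = rep(c(-150, 150), 6), kappa = 10, occupancy = 0.3),
    list(centers = rep(c(60, 45), 6), kappa = 10, occupancy = 0.1))
  traj <- sim_dihedral_traj(states, n_frames = 50000, n_residues = 6,
                            seed = 66)
  fep <- free_energy_surface(dpca_project(dihedral_features(traj)))
  mins <- find_minima(fep, depth_threshold = 0.5)
  expect_identical(nrow(mins), 3L)
  # occupancy-integrated basin free energies recover all pairwise
  # -ln(p_i / p_j) gaps with plain multinomial error
  basins <- basin_free_energies(fep, depth_threshold = 0.5)
  expect_identical(nrow(basins), 3L)
  expect_lt(abs(basins$deltaG[2] - log(0.6 / 0.3)), 0.1)
  expect_lt(abs(basins$deltaG[3] - log(0.6 / 0.1)), 0.1)
  expect_lt(abs(basins$occupancy[1] - 0.6), 0.02)

  # near-uniform occupancy: no minima above the depth threshold
  set.seed(67)
  flat <- tibble::tibble(V1 = runif(50000), V2 = runif(50000))
  fep_flat <- free_energy_surface(flat, bins = 10)
  expect_identical(nrow(find_minima(fep_flat, depth_threshold = 0.5)), 0L)
})
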