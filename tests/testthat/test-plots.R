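test_that("autoplot methods return ggplot objects for every result type", {
  cv <- sim_fd_curves(fd_params(n_curves = 4, specific_fraction = 0.5,
                                nonspecific_fraction = 0), seed = 81)
  expect_s3_class(autoplot(cv), "ggplot")

  set.seed(82)
  expect_s3_class(autoplot(fit_gaussian_hist(rnorm(100, 164, 17))), "ggplot")

  traj <- two_state_traj(2000, seed = 83)
  fep <- free_energy_surface(dpca_project(dihedral_features(traj)))
  expect_s3_class(autoplot(fep), "ggplot")

  tr <- mc_pull(cg_dimer("HM"), sweeps = 500, seed = 84)
  expect_s3_class(autoplot(tr), "ggplot")

  topo <- sim_topograph(topo_cap(20, 20, 2, 8), grid_px = 40, pixel_nm = 1)
  expect_s3_class(autoplot(topo), "ggplot")
})
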