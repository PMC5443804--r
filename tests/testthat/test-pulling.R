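test_that("dimer builders carry the reported contact counts and sequences", {
  hm <- cg_dimer("HM")
  # 5 hydrogen-bond contacts + 1 salt bridge between the chains
  expect_identical(sum(hm$contacts$class == "inter"), 5L)
  expect_identical(sum(hm$contacts$class == "saltbridge"), 1L)
  expect_identical(sum(hm$contacts$class == "intra"), 3L)
  expect_identical(as.integer(table(hm$chain)), c(25L, 11L))
  hh <- cg_dimer("HH")
  expect_identical(sum(hh$contacts$class == "inter"), 4L)
  expect_identical(as.integer(table(hh$chain)), c(25L, 25L))
  # salt bridge carries double depth
  expect_identical(hm$contacts$depth[hm$contacts$class == "saltbridge"],
                   2 * hm$contacts$depth[hm$contacts$class == "inter"][1])
  # pulling groups on distinct chains, first bead of each
  expect_identical(hm$pulling_groups, c(1L, 26L))
})

test_that("Go energy is additive, harmonic in bonds, finite everywhere", {
  hm <- cg_dimer("HM")
  # native geometry: bonds at rest, every contact at its minimum
  expect_equal(cg_energy(hm), -sum(hm$contacts$depth))

  # stretching one terminal bond by delta raises the energy by k delta^2 / 2
  co <- hm$coords
  delta <- 0.05
  bond1 <- hm$bonds[hm$bonds$i == 1, ]
  dir <- (co[1, ] - co[2, ]) / sqrt(sum((co[1, ] - co[2, ])^2))
  co[1, ] <- co[1, ] + dir * delta
  expect_equal(cg_energy(hm, co) - cg_energy(hm),
               0.5 * bond1$k * delta^2, tolerance = 1e-6)

  # removing a contact record raises the minimum energy by its depth
  hm2 <- hm
  hm2$contacts <- hm$contacts[-1, ]
  expect_equal(cg_energy(hm2) - cg_energy(hm), hm$contacts$depth[1])

  # overlapping beads: large but finite
  co_bad <- hm$coords
  co_bad[30, ] <- co_bad[5, ]
  e <- cg_energy(hm, co_bad)
  expect_true(is.finite(e))
  expect_gt(e, 1e3)
})

test_that("pulling runs are seeded, validated, and rupture sensibly", {
  hm <- cg_dimer("HM")
  a <- mc_pull(hm, seed = 3, sweeps = 2000)
  b <- mc_pull(hm, seed = 3, sweeps = 2000)
  expect_identical(a$rupture_force, b$rupture_force)
  expect_identical(a$trace, b$trace)

  expect_error(mc_pull(hm, k_spring = -1), class = "smc_param_error")
  expect_error(mc_pull(hm, contact_break_fraction = 1.5),
               class = "smc_param_error")

  # without inter-chain cohesion there is nothing to rupture
  free <- hm
  free$contacts <- dplyr::filter(hm$contacts, class == "intra")
  tr <- mc_pull(free, seed = 1)
  expect_lt(tr$rupture_force, 3 * sqrt(kBT(298) * 25))

  # rupture force equals the pre-rupture force maximum
  full <- mc_pull(hm, seed = 5)
  expect_false(is.na(full$rupture_sweep))
  expect_equal(full$rupture_force,
               max(full$trace$force[seq_len(full$rupture_sweep - 1)]))
})

test_that("the stronger intercalated dimer out-pulls the sheet dimer", {
  hm <- cg_dimer("HM")
  hh <- cg_dimer("HH")
  fhm <- pull_batch(hm, seeds = 1:10)$rupture_force
  fhh <- pull_batch(hh, seeds = 1:10)$rupture_force
  expect_gt(mean(fhm), mean(fhh))
  # doubling the velocity does not lower the mean rupture force
  fast <- pull_batch(hm, seeds = 1:10, velocity = 0.004)$rupture_force
  expect_gte(mean(fast), mean(fhm))
})

test_that("rupture statistics summarise per-trace forces", {
  st <- rupture_stats(c(100, 120))
  expect_equal(st$mean, 110)
  expect_equal(st$sd, 14.14, tolerance = 1e-3)
  expect_equal(rupture_stats(c(90, 90, 90))$sd, 0)
  expect_error(rupture_stats(100), class = "smc_param_error")
})
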