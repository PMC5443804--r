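test_that("worm-like-chain force law satisfies its analytic identities", {
  expect_identical(wlc_force(0, Lp = 0.38, Lc = 33), 0)
  # x = Lc/2: bracket evaluates to 1/4 * 4 - 1/4 + 1/2 = 1.25
  expect_equal(wlc_force(16.5, Lp = 0.38, Lc = 33),
               1.25 * kBT(298) / 0.38)
  # hand evaluation at kBT = 4.114 pN nm: 4.114 / 0.38 * 1.25 = 13.53
  expect_equal(wlc_force(16.5, Lp = 0.38, Lc = 33), 13.53, tolerance = 1e-3)
})

test_that("force is strictly increasing on [0, Lc) and diverges near Lc", {
  x <- seq(0, 32.99, length.out = 500)
  f <- wlc_force(x, Lp = 0.38, Lc = 33)
  expect_true(all(diff(f) > 0))
  expect_gt(wlc_force(33 * (1 - 1e-6), Lp = 0.38, Lc = 33), 1e6)
  expect_error(wlc_force(33, Lp = 0.38, Lc = 33), class = "smc_domain_error")
  expect_error(wlc_force(40, Lp = 0.38, Lc = 33), class = "smc_domain_error")
  expect_error(wlc_force(1, Lp = 2, Lc = 1), class = "smc_param_error")
})

test_that("numerical inversion round-trips the force law", {
  forces <- c(0, 5, 20, 100, 164, 500)
  x <- wlc_extension(forces, Lp = 0.38, Lc = 33)
  expect_equal(wlc_force(x[1], 0.38, 33), 0)
  expect_equal(wlc_force(x[-1], 0.38, 33), forces[-1], tolerance = 1e-6)
  expect_true(all(x >= 0 & x < 33))
})
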