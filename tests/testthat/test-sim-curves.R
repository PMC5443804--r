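test_that("generator yields the requested specific-event count and labels", {
  # 2000 cycles at 9% yield: 180 labelled specific curves
  cv <- sim_fd_curves(fd_preset("HM", n_curves = 2000, sampling_rate = 500),
                      seed = 1)
  expect_identical(sum(cv$type == "specific"), 180L)
  expect_true(all(is.na(cv$fr_true[cv$type != "specific"])))
  expect_true(all(cv$fr_true[cv$type == "specific"] > 0))
  # HH preset: 175 of 2000
  cv2 <- sim_fd_curves(fd_preset("HH", n_curves = 2000, sampling_rate = 500),
                       seed = 1)
  expect_identical(sum(cv2$type == "specific"), 175L)
})

test_that("fixed seed reproduces curves bitwise; parameters are validated", {
  p <- fd_params(n_curves = 10)
  a <- sim_fd_curves(p, seed = 7)
  b <- sim_fd_curves(p, seed = 7)
  expect_identical(a$curve, b$curve)
  expect_identical(a$fr_true, b$fr_true)
  expect_error(fd_params(specific_fraction = 0.7, nonspecific_fraction = 0.5),
               class = "smc_param_error")
  expect_error(fd_params(lc_sd = 40, lc_mean = 33), class = "smc_param_error")
  expect_error(fd_params(lp = -1), class = "smc_param_error")
})

test_that("degenerate widths give exact rupture forces on the WLC ramp", {
  p <- fd_params(n_curves = 20, rupture_sd = 0, noise_sd = 0, lc_sd = 1e-9,
                 specific_fraction = 1, nonspecific_fraction = 0)
  cv <- sim_fd_curves(p, seed = 2)
  expect_true(all(cv$fr_true == 164))
  # the last on-ramp sample force approaches the rupture force
  for (i in 1:3) {
    crv <- cv$curve[[i]]
    on <- crv$force_pN > 0
    expect_equal(max(crv$force_pN[on]), 164, tolerance = 0.05)
  }
})

test_that("ground-truth moments converge to the generator settings", {
  p <- fd_params(n_curves = 10000, specific_fraction = 1,
                 nonspecific_fraction = 0, sampling_rate = 100)
  cv <- sim_fd_curves(p, seed = 3)
  fr <- cv$fr_true
  se_mean <- 17 / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 164), 3 * se_mean)
  se_sd <- 17 / sqrt(2 * (length(fr) - 1))
  expect_lt(abs(sd(fr) - 17), 3 * se_sd)
  se_lc <- 5 / sqrt(length(fr))
  expect_lt(abs(mean(cv$lc_true) - 33), 3 * se_lc)
})
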