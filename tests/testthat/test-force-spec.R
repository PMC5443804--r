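test_that("rupture detection finds the drop and ignores non-events", {
  # noise-only curves: no event in at least 99%
  p <- fd_params(n_curves = 300, specific_fraction = 0,
                 nonspecific_fraction = 0)
  cv <- sim_fd_curves(p, seed = 11)
  hits <- sum(vapply(cv$curve, function(c) nrow(detect_rupture(c)) > 0,
                     logical(1)))
  expect_lte(hits, 3)

  # nonspecific short-range adhesion is excluded
  pn <- fd_params(n_curves = 50, specific_fraction = 0,
                  nonspecific_fraction = 1)
  cvn <- sim_fd_curves(pn, seed = 12)
  hits_n <- sum(vapply(cvn$curve, function(c) nrow(detect_rupture(c)) > 0,
                       logical(1)))
  expect_identical(hits_n, 0L)

  # specific curves: detected drop within one sample of the true rupture
  ps <- fd_params(n_curves = 30, specific_fraction = 1,
                  nonspecific_fraction = 0)
  cvs <- sim_fd_curves(ps, seed = 13)
  dx <- 500 / ps$sampling_rate
  for (i in 1:10) {
    det <- detect_rupture(cvs$curve[[i]])
    expect_identical(nrow(det), 1L)
    expect_lt(abs(det$x_rupture - cvs$x_rupture_true[i]), dx)
  }
})

test_that("WLC fitting round-trips exact ramps and tolerates noise", {
  # noise-free ramp: parameters recovered to <= 0.1% relative error
  x <- seq(2, wlc_extension(164, 0.38, 33), by = 0.1)
  seg <- tibble::tibble(distance_nm = x,
                        force_pN = wlc_force(x, 0.38, 33))
  fit <- fit_wlc(seg, x_rupture = max(x))
  expect_lt(abs(fit$Lp - 0.38) / 0.38, 1e-3)
  expect_lt(abs(fit$Lc - 33) / 33, 1e-3)

  # with 10 pN noise, Lc is recovered within 10% (Monte Carlo, 100 seeds)
  err <- vapply(1:100, function(s) {
    set.seed(s)
    segn <- seg
    segn$force_pN <- segn$force_pN + rnorm(nrow(seg), 0, 10)
    abs(fit_wlc(segn, x_rupture = max(x))$Lc - 33) / 33
  }, numeric(1))
  expect_lt(stats::median(err), 0.1)
  expect_gt(mean(err < 0.1), 0.9)

  # degenerate flat segment
  flat <- tibble::tibble(distance_nm = x, force_pN = rep(0, length(x)))
  expect_error(fit_wlc(flat, x_rupture = max(x)), class = "smc_fit_error")
})

test_that("specificity filter applies the contour-length window and noise floor", {
  ev <- tibble::tibble(Fr = c(164, 150, 15, 120), Lc = c(31, 80, 33, 24))
  kept <- filter_specific(ev, lc_window = c(23, 43), noise_floor = 20)
  expect_identical(kept$Lc, c(31, 24))
  expect_identical(attr(kept, "n_rejected"), 2L)
  expect_lte(nrow(kept), nrow(ev))
  empty <- filter_specific(ev[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("Gaussian histogram fit recovers the sample location", {
  set.seed(21)
  vals <- rnorm(180, 164, 17)
  fit <- fit_gaussian_hist(vals)
  expect_lt(abs(fit$mean - 164), 3 * 17 / sqrt(180))
  expect_identical(fit$n, 180L)

  # all-identical values: single populated bin, no fit
  expect_error(fit_gaussian_hist(rep(100, 50)), class = "smc_fit_error")
  expect_error(fit_gaussian_hist(rnorm(10)), class = "smc_fit_error")

  # symmetric bimodal sample: the single-Gaussian fit is flagged poor
  # by its residual (least squares latches onto one mode rather than
  # averaging the two, so the location is only required to stay within
  # the data range)
  set.seed(22)
  bim <- c(rnorm(200, 100, 5), rnorm(200, 200, 5))
  bfit <- fit_gaussian_hist(bim)
  expect_gte(bfit$mean, min(bim))
  expect_lte(bfit$mean, max(bim))
  uni <- fit_gaussian_hist(rnorm(400, 150, 5))
  expect_gt(bfit$relative_rss, 5 * uni$relative_rss)
})

test_that("replicate aggregation and KS comparison behave as reported", {
  agg <- aggregate_replicates(c(150, 164, 178))
  expect_equal(agg$mean, 164)
  expect_equal(agg$sd, 14)
  expect_equal(aggregate_replicates(c(164, 164, 164))$sd, 0)
  expect_error(aggregate_replicates(164), class = "smc_param_error")

  x <- rnorm(50, 0, 1)
  same <- ks_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_compare(1:30, 101:130)
  expect_equal(disjoint$statistic, 1)
  expect_error(ks_compare(rnorm(5), rnorm(50)), class = "smc_param_error")
})

test_that("tidiers expose fits as tibbles", {
  set.seed(31)
  fit <- fit_gaussian_hist(rnorm(100, 10, 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$term, c("mean", "sd"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  x <- seq(2, 25, by = 0.1)
  wf <- fit_wlc(tibble::tibble(distance_nm = x,
                               force_pN = wlc_force(x, 0.38, 33)),
                x_rupture = 25)
  expect_identical(tidy(wf)$term, c("Fr", "Lc", "Lp"))
})
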