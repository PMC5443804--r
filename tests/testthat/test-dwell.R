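test_that("burst detection returns one-step events with quantized dwells", {
  set.seed(41)
  y <- rnorm(600, 0, 3)
  y[100:104] <- y[100:104] + 100  # 5 frames at 100 ms = 500 ms dwell
  ev <- detect_bursts(y, frame_ms = 100)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$dwell_ms, 500)
  expect_identical(ev$start_frame, 100L)

  # flat background: zero events
  expect_identical(nrow(detect_bursts(rnorm(600, 0, 3), frame_ms = 100)), 0L)

  # staircase (two rises before the fall) is rejected as not one-step
  y2 <- rnorm(600, 0, 3)
  y2[100:104] <- y2[100:104] + 50
  y2[105:109] <- y2[105:109] + 100
  expect_identical(nrow(detect_bursts(y2, frame_ms = 100)), 0L)

  # boundary-touching runs are censored
  y3 <- rnorm(600, 0, 3)
  y3[1:5] <- y3[1:5] + 100
  y3[596:600] <- y3[596:600] + 100
  expect_identical(nrow(detect_bursts(y3, frame_ms = 100)), 0L)

  # saturated (zero-spread) traces are analysis errors
  expect_error(detect_bursts(rep(5, 600)), class = "smc_analysis_error")
})

test_that("trace generator injects the requested events with frame quantization", {
  p <- trace_preset("HM", n_traces = 10, n_events = 50)
  tr <- sim_intensity_traces(p, seed = 42)
  truth <- attr(tr, "truth")
  expect_identical(nrow(truth), 50L)
  # every quantized dwell is an integral multiple of the frame and
  # within one frame of the true dwell
  expect_true(all(truth$dwell_ms %% 100 == 0))
  expect_true(all(abs(truth$dwell_ms - truth$dwell_true_ms) < 100))
  # determinism
  tr2 <- sim_intensity_traces(p, seed = 42)
  expect_identical(tr$trace, tr2$trace)
  # sub-resolution flagging
  psub <- trace_params(n_traces = 2, n_events = 20, dwell_mean_ms = 30,
                       dwell_sigma = 0.2)
  sub <- attr(sim_intensity_traces(psub, seed = 1), "truth")
  expect_true(all(sub$sub_resolution))
  expect_true(all(sub$dwell_ms == 100))
  expect_error(trace_params(frame_ms = 100, duration_s = 0.15),
               class = "smc_param_error")
})

test_that("lognormal fit recovers the distribution mean", {
  # truth from the H-M lifetime: distribution mean 617 ms
  set.seed(43)
  sigma <- 0.8
  d <- rlnorm(297, log(617) - sigma^2 / 2, sigma)
  d <- pmax(100, round(d / 100) * 100)  # frame quantization
  fit <- fit_lognormal(d)
  se <- 617 * sqrt(exp(sigma^2) - 1) / sqrt(297)
  expect_lt(abs(fit$mean_ms - 617), 3 * se)
  mle <- fit_lognormal(d, method = "mle")
  expect_lt(abs(mle$mean_ms - 617), 3 * se)

  # degenerate sample: all equal dwells give that exact mean
  expect_equal(fit_lognormal(rep(400, 30))$mean_ms, 400)
  expect_equal(fit_lognormal(rep(400, 30))$log_sigma, 0)

  expect_error(fit_lognormal(c(d, -5)), class = "smc_param_error")
  expect_error(fit_lognormal(d[1:5]), class = "smc_fit_error")
})

test_that("lifetime pipeline recovers counts and is robust to frame width", {
  tr <- sim_intensity_traces(trace_preset("HM", n_traces = 20,
                                          n_events = 120), seed = 44)
  res <- lifetime_pipeline(tr)
  expect_identical(res$n_events, 120L)
  expect_s3_class(glance(res), "tbl_df")

  # quantization bias is bounded by one frame: recovered means at 10 ms
  # and 100 ms frames agree within 100 ms
  p100 <- trace_params(n_traces = 20, frame_ms = 100, duration_s = 150,
                       dwell_mean_ms = 617, n_events = 150)
  p10 <- trace_params(n_traces = 20, frame_ms = 10, duration_s = 150,
                      dwell_mean_ms = 617, n_events = 150)
  m100 <- lifetime_pipeline(sim_intensity_traces(p100, seed = 45))$fit$mean_ms
  m10 <- lifetime_pipeline(sim_intensity_traces(p10, seed = 45))$fit$mean_ms
  expect_lt(abs(m100 - m10), 100)

  # burst-free traces are an analysis error
  flat <- sim_intensity_traces(trace_params(n_traces = 3, burst_rate = 0),
                               seed = 46)
  expect_error(lifetime_pipeline(flat), class = "smc_analysis_error")

  # false-event rate on noise-only traces under 1% per trace
  noise <- sim_intensity_traces(trace_params(n_traces = 100, burst_rate = 0),
                                seed = 47)
  n_false <- sum(vapply(noise$trace, function(t)
    nrow(detect_bursts(t, frame_ms = 100)), numeric(1)))
  expect_lte(n_false, 1)
})
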