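test_that("cross-sections read feature heights off the map", {
  # noise-free fibril of apex 6 nm: perpendicular section reads 6 nm
  ft <- topo_fibril(10, 50.5, 90, 50.5, height = 6, width = 46)
  topo <- sim_topograph(ft, grid_px = 100, pixel_nm = 1, roughness_sd = 0)
  cs <- cross_section(topo, c(51, 15), c(51, 86))
  expect_equal(cs$peak_height, 6, tolerance = 0.01)
  expect_gt(cs$fwhm_nm, 30)  # tip-convolved width, not the true core

  # flat map: zero peak
  flat <- sim_topograph(grid_px = 64, pixel_nm = 1, roughness_sd = 0)
  expect_equal(cross_section(flat, c(10, 10), c(50, 50))$peak_height, 0)

  # spherical cap of 2.65 nm through its centre
  cap <- sim_topograph(topo_cap(32.5, 32.5, 2.65, 10), grid_px = 64,
                       pixel_nm = 1, roughness_sd = 0)
  cs2 <- cross_section(cap, c(33, 5), c(33, 60))
  expect_equal(cs2$peak_height, 2.65, tolerance = 0.02)

  expect_error(cross_section(cap, c(10, 10), c(10, 10)),
               class = "smc_param_error")
})

test_that("cap sections match the analytic spherical profile", {
  h <- 2.65; a <- 10
  # cap centred on a pixel centre so the section row passes the apex
  topo <- sim_topograph(topo_cap(61, 61, h, a), grid_px = 60,
                        pixel_nm = 2, roughness_sd = 0)
  cs <- cross_section(topo, c(31, 6), c(31, 56), n = 200)
  rs <- (a^2 + h^2) / (2 * h)
  r <- abs(cs$profile$position_nm - 50)
  z_true <- ifelse(r <= a, pmax(sqrt(pmax(rs^2 - r^2, 0)) - (rs - h), 0), 0)
  # on the smooth interior the bilinear profile tracks the sphere to
  # within curvature * pixel^2 / 8; the rim kink is O(slope * pixel)
  # for any linear interpolation and is checked with its own bound
  interior <- r <= a - 2 * 2
  expect_lt(max(abs(cs$profile$height_nm - z_true)[interior]), 0.05)
  expect_lt(max(abs(cs$profile$height_nm - z_true)), 0.3)
})

test_that("particle detection labels isolated and merged regions", {
  fld <- feature_field("cap", n = 100, seed = 51)
  topo <- sim_topograph(fld$features, grid_px = fld$grid_px, pixel_nm = 1,
                        roughness_sd = 0.05, seed = 52)
  pt <- detect_particles(topo, min_height = 0.5)
  expect_identical(nrow(pt), 100L)

  # empty topograph
  empty <- sim_topograph(grid_px = 64, pixel_nm = 1, roughness_sd = 0.05)
  expect_identical(nrow(detect_particles(empty, min_height = 0.5)), 0L)

  # two overlapping caps merge into one region
  two <- dplyr::bind_rows(topo_cap(30, 32, 2, 8), topo_cap(40, 32, 2.5, 8))
  t2 <- sim_topograph(two, grid_px = 64, pixel_nm = 1, roughness_sd = 0)
  expect_identical(nrow(detect_particles(t2, min_height = 0.5)), 1L)
})

test_that("height statistics recover generator truth and ignore offsets", {
  fld <- feature_field("cap", n = 100, mean_h = 2.65, sd_h = 0.61, seed = 53)
  topo <- sim_topograph(fld$features, grid_px = fld$grid_px, pixel_nm = 1,
                        roughness_sd = 0.05, seed = 54)
  st <- height_stats(detect_particles(topo, min_height = 0.5))
  expect_lt(abs(st$mean - mean(fld$heights)), 3 * 0.61 / sqrt(100))

  dld <- feature_field("disk", n = 100, mean_h = 0.85, sd_h = 0.08, seed = 55)
  topo_d <- sim_topograph(dld$features, grid_px = dld$grid_px, pixel_nm = 1,
                          roughness_sd = 0.05, seed = 56)
  st_d <- height_stats(detect_particles(topo_d, min_height = 0.3))
  expect_lt(abs(st_d$mean - mean(dld$heights)), 3 * 0.08 / sqrt(100))

  # adding a constant plane leaves heights unchanged (baseline subtraction)
  topo_off <- topo
  topo_off$heights <- topo_off$heights + 7.3
  st_off <- height_stats(detect_particles(topo_off, min_height = 0.5))
  expect_equal(st_off$mean, st$mean, tolerance = 1e-10)

  # single particle: mean = height, sd = 0
  one <- height_stats(tibble::tibble(height_nm = 2.1,
                                     touches_border = FALSE))
  expect_identical(one$mean, 2.1)
  expect_identical(one$sd, 0)
  expect_error(height_stats(tibble::tibble(height_nm = numeric())),
               class = "smc_param_error")
})
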