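test_that("decay sampling follows the activity distribution", {
  g <- small_geom()
  grid <- fov_grid(g, 2)

  one <- grid
  one$values[5, 11] <- 3
  set.seed(1)
  p <- sample_decays(one, 200)
  cc <- pixel_centers(grid)
  expect_true(all(abs(p[, 1] - cc$x[5]) <= 1))
  expect_true(all(abs(p[, 2] - cc$y[11]) <= 1))
  expect_equal(nrow(sample_decays(one, 5)), 5L)

  two <- grid
  two$values[3, 3] <- 1
  two$values[6, 6] <- 3
  set.seed(2)
  p <- sample_decays(two, 40000)
  n1 <- sum(p[, 1] < cc$x[4])
  # exact binomial 99% CI around 1/4
  ci <- qbinom(c(0.005, 0.995), 40000, 0.25)
  expect_gt(n1, ci[1])
  expect_lt(n1, ci[2])

  expect_error(sample_decays(grid, 10), "empty source")
})

test_that("coincidence tracing geometry and timing", {
  g <- panel_geometry()
  # origin, vertical rays: central crystals, delta_t = 0
  tr <- trace_coincidence(g, c(0, 0), pi / 2)
  expect_true(tr$crystal_a %in% c(69L, 70L))
  expect_equal(tr$crystal_a, tr$crystal_b)
  expect_equal(tr$true_delta_t, 0)

  # horizontal rays never make a coincidence
  tr0 <- trace_coincidence(g, c(0, 0), 0)
  expect_true(is.na(tr0$crystal_a))

  # (0, +50): path difference (100 - 200) mm -> -333.6 ps
  tr50 <- trace_coincidence(g, c(0, 50), pi / 2)
  expect_equal(tr50$true_delta_t, -100 / 0.299792458, tolerance = 1e-12)

  expect_error(trace_coincidence(g, c(0, 200), pi / 2), "outside the field")
})

test_that("blur has the requested Gaussian width and degenerates cleanly", {
  set.seed(3)
  b0 <- blur_events(rep(100, 10), 0, 0)
  expect_equal(b0$delta_t, rep(100, 10))
  expect_equal(b0$energy_a, rep(511, 10))

  b <- blur_events(rep(0, 1e5), 300, 0.13)
  expect_equal(sd(b$delta_t), 300 / (2 * sqrt(2 * log(2))), tolerance = 0.02)
  expect_equal(sd(b$energy_a), 0.13 * 511 / (2 * sqrt(2 * log(2))),
               tolerance = 0.02)
})

test_that("acquisition windows accept and reject correctly", {
  expect_true(apply_windows(0, 511, 511))
  expect_false(apply_windows(0, 399, 511))
  expect_false(apply_windows(6001, 511, 511))
  expect_true(apply_windows(6000, 511, 511))

  # acceptance fraction at 13% energy resolution: per photon the Gaussian
  # mass between 400 and 600 keV, squared for the pair
  sig_e <- 0.13 * 511 / (2 * sqrt(2 * log(2)))
  p1 <- pnorm((600 - 511) / sig_e) - pnorm((400 - 511) / sig_e)
  set.seed(4)
  b <- blur_events(rep(0, 2e5), 0, 0.13)
  acc <- mean(apply_windows(b$delta_t, b$energy_a, b$energy_b))
  expect_equal(acc, p1^2, tolerance = 0.002)
})

test_that("windows are monotone in narrowing", {
  set.seed(5)
  b <- blur_events(rnorm(2e4, 0, 400), 300, 0.13)
  wide <- sum(apply_windows(b$delta_t, b$energy_a, b$energy_b,
                            c(400, 600), 6000))
  nar_e <- sum(apply_windows(b$delta_t, b$energy_a, b$energy_b,
                             c(450, 570), 6000))
  nar_t <- sum(apply_windows(b$delta_t, b$energy_a, b$energy_b,
                             c(400, 600), 500))
  expect_lte(nar_e, wide)
  expect_lte(nar_t, wide)
})

test_that("list-mode simulation is reproducible and geometrically sound", {
  g <- panel_geometry()
  grid <- fov_grid(g, 1)
  src <- grid
  src$values[141, 151] <- 1   # pixel centred at (0.5, 0.5)

  cfg <- acquisition_config(2e4, timing_fwhm = 0, energy_fwhm_fraction = 0,
                            seed = 7)
  lm1 <- simulate_listmode(src, g, cfg)
  lm2 <- simulate_listmode(src, g, cfg)
  expect_identical(lm1, lm2)

  # struck crystals always within the panel
  expect_true(all(lm1$events$crystal_a >= 0 & lm1$events$crystal_a < 140))
  expect_true(all(lm1$events$crystal_b >= 0 & lm1$events$crystal_b < 140))

  # with perfect timing, the TOF position reproduces the source x within
  # one crystal pitch discretization error
  pos <- tof_position(g, lm1$events$crystal_a, lm1$events$crystal_b,
                      lm1$events$delta_t)
  expect_lt(max(abs(pos[, "x"] - lm1$events$true_x)), g$crystal_pitch)
})

test_that("geometric efficiency of a central point source matches the 2D acceptance", {
  g <- panel_geometry()
  grid <- fov_grid(g, 1)
  src <- grid
  src$values[140, 150] <- 1   # pixel just left/below the origin
  cfg <- acquisition_config(4e5, timing_fwhm = 0, energy_fwhm_fraction = 0,
                            seed = 8)
  lm <- simulate_listmode(src, g, cfg)
  expect_equal(n_events(lm) / cfg$n_decays, (2 / pi) * atan(140 / 150),
               tolerance = 0.01)
})

test_that("post-hoc re-blurring is distributionally identical to direct simulation", {
  g <- mid_geom()
  act <- disc_activity(g)
  base <- simulate_listmode(act, g, acquisition_config(1.2e5, 0, 0, seed = 9))
  reb <- reblur_listmode(base, timing_fwhm = 350, seed = 10)
  direct <- simulate_listmode(act, g,
                              acquisition_config(1.2e5, 350, seed = 11))
  ks <- suppressWarnings(ks.test(reb$events$delta_t, direct$events$delta_t))
  expect_gt(ks$p.value, 0.01)
  expect_error(reblur_listmode(reb, 100), "perfect-resolution")
})
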