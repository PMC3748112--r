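test_that("ROI event discrimination matches an independent re-evaluation", {
  g <- mid_geom()
  lm <- quick_listmode(g, n_decays = 1.5e4, timing_fwhm = 300, seed = 21)
  roi <- roi_window(-20, 14, -18, 22)
  kept <- filter_events_roi(lm, g, roi)

  # independent arithmetic: d = c dt / 2 from the midpoint toward the
  # bottom crystal, half-open ROI test
  ev <- lm$events
  cc <- -32 + (0:31 + 0.5) * 2
  ax <- cc[ev$crystal_a + 1]; bx <- cc[ev$crystal_b + 1]
  ell <- sqrt((bx - ax)^2 + 80^2)
  d <- 0.299792458 * ev$delta_t / 2
  px <- (ax + bx) / 2 + d * (bx - ax) / ell
  py <- 0 + d * (-80) / ell
  keep <- px >= -20 & px < 14 & py >= -18 & py < 22
  expect_identical(kept$events$seq, ev$seq[keep])
  expect_equal(kept$meta$roi_filter$kept, sum(keep))
  expect_equal(kept$meta$roi_filter$total, nrow(ev))

  # midpoint event on a LOR whose midpoint is inside the ROI is kept
  mid_ev <- manual_listmode(g, 15L, 15L, 0)
  expect_equal(nrow(filter_events_roi(mid_ev, g, roi)$events), 1L)

  # ROI covering the whole FOV only drops events mapped outside the FOV
  fkeep <- filter_events_roi(lm, g, fov_window(g))
  pos <- tof_position(g, ev$crystal_a, ev$crystal_b, ev$delta_t)
  expect_equal(nrow(fkeep$events), sum(point_in_roi(fov_window(g), pos)))
})

test_that("chronological subset partition sizes and order", {
  g <- mid_geom()
  lm32 <- manual_listmode(g, rep(3L, 32), rep(3L, 32), rnorm(32, 0, 50))
  p <- partition_subsets(lm32, 16)
  expect_length(p, 16L)
  expect_true(all(lengths(p) == 2L))
  expect_equal(unlist(p, use.names = FALSE), 1:32)

  p33 <- partition_subsets(33, 16)
  expect_equal(lengths(p33)[1], 3L)
  expect_true(all(lengths(p33)[-1] == 2L))

  p1 <- partition_subsets(lm32, 1)
  expect_equal(p1[[1]], 1:32)

  expect_error(partition_subsets(10, 16), "fewer subsets")
})

test_that("EM count preservation after full one-subset updates", {
  g <- mid_geom()
  grid <- fov_grid(g, 2)
  lm <- quick_listmode(g, n_decays = 8e3, timing_fwhm = 250, seed = 22)
  fdata <- filter_events_roi(lm, g, fov_window(g))
  k <- tof_kernel(250)
  cache <- build_system_cache(g, grid)
  sens <- sensitivity_windowed(g, grid, k, fov_window(g), cache = cache)
  img <- pet_image(matrix(1 * (sens$values > 0), nrow(sens$values),
                          ncol(sens$values)), 2, grid$origin)
  K <- nrow(fdata$events)
  for (it in 1:3) {
    up <- em_update(img, fdata, g, k, sens, cache = cache)
    img <- up$image
    expect_equal(up$skipped, 0L)
    expect_lt(abs(sum(sens$values * img$values) - K) / K, 1e-6)
  }
})

test_that("EM preserves mirror symmetry and non-negativity", {
  g <- mid_geom()
  grid <- fov_grid(g, 2)
  k <- tof_kernel(300)
  cache <- build_system_cache(g, grid)
  sens <- sensitivity_windowed(g, grid, k, fov_window(g), cache = cache)

  # mirror-symmetric event set about x = 0
  a <- c(5L, 26L, 10L, 21L, 15L, 16L)
  b <- c(8L, 23L, 12L, 19L, 16L, 15L)
  dt <- c(100, 100, -250, -250, 0, 0)
  lm <- manual_listmode(g, a, b, dt)
  img <- pet_image(matrix(1 * (sens$values > 0), 32, 40), 2, grid$origin)
  up <- em_update(img, lm, g, k, sens, cache = cache)
  v <- up$image$values
  expect_true(all(v >= 0))
  expect_lt(max(abs(v - v[32:1, ])), 1e-10 * max(v))
  # zero-sensitivity pixels stay exactly zero
  expect_true(all(v[sens$values == 0] == 0))
})

test_that("list-mode OSEM matches a dense-matrix EM on a small instance", {
  g <- small_geom()
  grid <- list(nx = 12L, ny = 12L, px = 1, x0 = -6, y0 = -6)
  gridimg <- pet_image(matrix(0, 12, 12), 1, c(-6, -6))
  act <- gridimg
  act$values[4:9, 4:9] <- 1
  act$values[6:7, 6:7] <- 4
  lm <- simulate_listmode(act, g, acquisition_config(2000, timing_fwhm = 200,
                                                     seed = 23))
  lm$events <- head(lm$events, 200)
  k <- tof_kernel(200)
  cache <- build_system_cache(g, gridimg)
  sens <- sensitivity_windowed(g, gridimg, k,
                               roi_window(-6, 6, -6, 6), cache = cache)
  fdata <- filter_events_roi(lm, g, roi_window(-6, 6, -6, 6))

  ref <- dense_em(fdata, g, gridimg, k, sens, n_iter = 3)
  img <- pet_image(matrix(1 * (sens$values > 0), 12, 12), 1, c(-6, -6))
  for (it in 1:3) {
    img <- em_update(img, fdata, g, k, sens, cache = cache)$image
    expect_lt(max(abs(as.numeric(img$values) - ref[[it]])), 1e-10)
  }
})

test_that("reconstruction is deterministic and windowed(FOV) equals conventional", {
  g <- mid_geom()
  lm <- quick_listmode(g, n_decays = 6e3, timing_fwhm = 300, seed = 24)
  cache <- build_system_cache(g, fov_grid(g, 2))
  r1 <- reconstruct_osem(lm, geom = g, pixel_size = 2, cache = cache,
                         n_iterations = 2, n_subsets = 4)
  r2 <- reconstruct_osem(lm, geom = g, pixel_size = 2, cache = cache,
                         n_iterations = 2, n_subsets = 4)
  expect_identical(r1$image$values, r2$image$values)

  rw <- reconstruct_windowed(lm, fov_window(g), geom = g, pixel_size = 2,
                             cache = cache, n_iterations = 2, n_subsets = 4)
  expect_identical(rw$image$values, r1$image$values)
  expect_equal(rw$counts$used, r1$counts$used)
})

test_that("windowed reconstruction uses fewer events and recovers a hot lesion", {
  g <- mid_geom()
  grid <- fov_grid(g, 2)
  act <- disc_activity(g, 2, diameter = 44)
  lesion <- rasterize_disc(grid, c(6, -4), 12)
  act$values[lesion] <- 4
  lm <- simulate_listmode(act, g, acquisition_config(6e4, 300, seed = 25))
  roi <- roi_window(-26, 26, -26, 26)
  cache <- build_system_cache(g, grid)
  rec <- reconstruct_windowed(lm, roi, geom = g, grid = grid, cache = cache,
                              n_iterations = 5, n_subsets = 8)
  expect_lt(rec$counts$used, rec$counts$total)

  v <- rec$image$values
  bgm <- rasterize_disc(grid, c(-10, 8), 16) & !lesion
  zl <- v[lesion]; zb <- v[bgm]
  z <- (mean(zl) - mean(zb)) /
    sqrt(var(zl) / length(zl) + var(zb) / length(zb))
  expect_gt(z, qnorm(0.99))

  # cropped ROI view is consistent with the full grid
  expect_equal(dim(rec$roi_image$values), c(26L, 26L))
  expect_error(reconstruct_windowed(lm, roi_window(-30, -29, 25, 26),
                                    geom = g, grid = grid, cache = cache),
               "no events")
})

test_that("log-likelihood: degenerate cases, scaling optimum, monotonicity", {
  g <- mid_geom()
  grid <- fov_grid(g, 2)
  lm <- quick_listmode(g, n_decays = 5e3, timing_fwhm = 250, seed = 26)
  fdata <- filter_events_roi(lm, g, fov_window(g))
  k <- tof_kernel(250)
  cache <- build_system_cache(g, grid)
  sens <- sensitivity_windowed(g, grid, k, fov_window(g), cache = cache)

  zero <- pet_image(matrix(0, 32, 40), 2, grid$origin)
  ll0 <- loglikelihood(zero, fdata, g, k, sens, cache = cache)
  expect_equal(as.numeric(ll0), -Inf)
  expect_equal(attr(ll0, "first_zero_event"), 1L)

  img <- pet_image(matrix(1 * (sens$values > 0), 32, 40), 2, grid$origin)
  K <- nrow(fdata$events)
  # LL(alpha * lambda) is maximized at alpha* = K / sum(s * lambda)
  astar <- K / sum(sens$values * img$values)
  lls <- vapply(c(0.5, 0.9, 1, 1.1, 2), function(f) {
    scaled <- img
    scaled$values <- img$values * (astar * f)
    as.numeric(loglikelihood(scaled, fdata, g, k, sens, cache = cache))
  }, numeric(1))
  expect_equal(which.max(lls), 3L)

  # full-EM updates never decrease the log-likelihood
  ll_prev <- as.numeric(loglikelihood(img, fdata, g, k, sens, cache = cache))
  for (it in 1:5) {
    img <- em_update(img, fdata, g, k, sens, cache = cache)$image
    ll <- as.numeric(loglikelihood(img, fdata, g, k, sens, cache = cache))
    expect_gte(ll, ll_prev - 1e-9 * abs(ll_prev))
    ll_prev <- ll
  }
})

test_that("point-source reconstruction localizes the source", {
  g <- mid_geom()
  grid <- fov_grid(g, 1)
  src <- grid
  src$values[44, 20] <- 1    # centre (11.5, -20.5)
  lm <- simulate_listmode(src, g, acquisition_config(6e4, 300, seed = 27))
  cache <- build_system_cache(g, grid)
  rec <- reconstruct_osem(lm, geom = g, grid = grid, cache = cache,
                          n_iterations = 5, n_subsets = 8)
  v <- rec$image$values
  cc <- pixel_centers(grid)
  cx <- sum(outer(cc$x, rep(1, length(cc$y))) * v) / sum(v)
  cy <- sum(outer(rep(1, length(cc$x)), cc$y) * v) / sum(v)
  expect_lt(sqrt((cx - 11.5)^2 + (cy + 20.5)^2), 1)
})
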