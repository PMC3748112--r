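test_that("TOF kernel derived quantities and normalization", {
  k <- tof_kernel(300)
  expect_equal(k$sigma_t, 300 / (2 * sqrt(2 * log(2))))
  expect_equal(k$sigma_x, 0.299792458 * k$sigma_t / 2)
  expect_equal(k$sigma_x, 19.10, tolerance = 1e-3)
  expect_equal(k$n_bins, 481L)
  expect_equal(sum(k$bin_centers), 0)

  # bin masses over the 6 ns window sum to 1 for FWHM up to 1 ns,
  # at any axis position within the FOV
  for (f in c(100, 300, 1000)) {
    kk <- tof_kernel(f)
    for (u in c(-140, 0, 77.3)) {
      expect_equal(sum(tof_bin_probabilities(kk, u)), 1, tolerance = 1e-6)
    }
  }

  # degenerate kernel: a single unit bin
  k0 <- tof_kernel(0)
  p <- tof_bin_probabilities(k0, 0)
  expect_equal(sum(p), 1)
  expect_equal(max(p), 1)
})

test_that("continuous TOF weight has Gaussian shape", {
  k <- tof_kernel(300)
  mode <- tof_weight(k, 0, 0)
  expect_equal(mode, 1 / (k$sigma_x * sqrt(2 * pi)))
  expect_equal(tof_weight(k, k$sigma_x, 0), mode * exp(-0.5))
})

test_that("Siddon traversal conserves chord length", {
  g <- small_geom()
  grid <- fov_grid(g, 1)

  # vertical segment: every traversed pixel has identical 1 mm raw length
  tr <- siddon_trace(grid, c(0.5, -30), c(0.5, 30))
  expect_equal(nrow(tr), 60L)
  expect_true(all(abs(tr$length - 1) < 1e-12))

  set.seed(12)
  for (i in 1:30) {
    from <- c(runif(1, -8, 8), 30)
    to <- c(runif(1, -8, 8), -30)
    tr <- siddon_trace(grid, from, to)
    expect_lt(abs(sum(tr$length) - sqrt(sum((to - from)^2))), 1e-9)
  }

  # segment missing the grid entirely
  expect_equal(nrow(siddon_trace(grid, c(50, 40), c(60, 45))), 0L)
})

test_that("geometric weights: totals, symmetry, column structure", {
  g <- small_geom()
  grid <- fov_grid(g, 1)
  cache <- build_system_cache(g, grid)

  # mirror symmetry in x: LOR (a,b) maps onto (n-1-a, n-1-b)
  n <- g$n_crystals_per_panel
  w1 <- geometric_weights(g, 1L, 3L, grid)
  w2 <- geometric_weights(g, n - 2L, n - 4L, grid)
  w2$ix_m <- nrow(grid$values) + 1L - w2$ix
  o1 <- order(w1$iy, w1$ix)
  o2 <- order(w2$iy, w2$ix_m)
  expect_equal(w1$ix[o1], w2$ix_m[o2])
  expect_equal(w1$weight[o1], w2$weight[o2], tolerance = 1e-12)

  # vertical pair on a crystal-aligned grid: weight constant within each
  # interior column strip
  wv <- geometric_weights(g, 4L, 4L, grid)
  mid_rows <- wv[wv$iy > 5 & wv$iy < 56, ]
  for (col in unique(mid_rows$ix)) {
    wcol <- mid_rows$weight[mid_rows$ix == col]
    expect_lt(diff(range(wcol)) / max(wcol), 1e-9)
  }
})

test_that("geometric sensitivity matches the 2D acceptance integral", {
  g <- small_geom()
  grid <- fov_grid(g, 1)
  cache <- build_system_cache(g, grid)
  gs <- geometric_sensitivity(cache)

  # central pixels: acceptance (1/pi) * angular measure; independent numeric
  # integration of the in-plane acceptance over the pixel
  acc_point <- function(x, y) {
    t_hi <- pmin((8 - x) / (30 - y), (x + 8) / (30 + y))
    t_lo <- pmax((-8 - x) / (30 - y), (x - 8) / (30 + y))
    pmax(0, atan(t_hi) - atan(t_lo)) / pi
  }
  qs <- seq(-0.45, 0.45, by = 0.1)
  for (pix in list(c(8L, 30L), c(5L, 20L), c(12L, 40L))) {
    cx <- -8 + pix[1] - 0.5
    cy <- -30 + pix[2] - 0.5
    ref <- mean(outer(cx + qs, cy + qs, acc_point))
    expect_equal(gs$values[pix[1], pix[2]], ref, tolerance = 0.01)
  }

  # strictly larger at the centre than near the panel edge at equal height
  expect_gt(gs$values[8, 30], gs$values[1, 30])
})

test_that("pixels outside the panel extent have zero sensitivity", {
  g <- small_geom()
  wide <- pet_image(matrix(0, 30, 20), 2, c(-30, -20))  # x beyond the panels
  cache <- build_system_cache(g, wide)
  gs <- geometric_sensitivity(cache)
  cc <- pixel_centers(wide)
  outside <- abs(cc$x) > 8
  expect_true(all(gs$values[outside, ] == 0))
  expect_true(all(gs$values[abs(cc$x) < 8, 8:13] > 0))
})

test_that("windowed sensitivity is dominated by and converges to the full one", {
  g <- small_geom()
  grid <- fov_grid(g, 1)
  cache <- build_system_cache(g, grid)
  k <- tof_kernel(300)

  s_full <- sensitivity_full(g, grid, k, cache = cache)
  roi_small <- roi_window(-4, 4, -10, 10)
  roi_big <- roi_window(-7, 7, -25, 25)
  s_small <- sensitivity_windowed(g, grid, k, roi_small, cache = cache)
  s_big <- sensitivity_windowed(g, grid, k, roi_big, cache = cache)

  expect_true(all(s_small$values <= s_full$values + 1e-12))
  expect_true(all(s_small$values <= s_big$values + 1e-12))
  expect_true(all(s_big$values <= s_full$values + 1e-12))

  # strict inequality where LORs extend well beyond the ROI
  expect_lt(s_small$values[8, 55], 0.5 * s_full$values[8, 55])

  # ROI = FOV reproduces the full sensitivity exactly (same computation)
  s_fov <- sensitivity_windowed(g, grid, k, fov_window(g), cache = cache)
  expect_identical(s_fov$values, s_full$values)

  # interior pixels, sharp kernel: TOF masses sum to ~1 there, so the full
  # sensitivity reduces to the plain geometric sum
  k30 <- tof_kernel(30)
  s30 <- sensitivity_full(g, grid, k30, cache = cache)
  gsv <- geometric_sensitivity(cache)$values
  expect_equal(s30$values[6:11, 25:35], gsv[6:11, 25:35],
               tolerance = 1e-10)
})

test_that("degenerate empty-overlap ROI yields zero sensitivity", {
  g <- small_geom()
  grid <- fov_grid(g, 2)
  k <- tof_kernel(300)
  # sliver ROI near a panel face: only a tiny share of any LOR's TOF mass
  roi <- roi_window(-0.5, 0.5, 28, 29.9)
  s <- sensitivity_windowed(g, grid, k, roi)
  expect_lt(max(s$values), 0.1 * max(sensitivity_full(g, grid, k)$values))
})

test_that("MC oracle basic consistency: symmetry and row sums", {
  g <- small_geom()
  grid <- list(nx = 12L, ny = 12L, px = 1, x0 = -6, y0 = -6)
  set.seed(13)
  mc <- mc_system_matrix_oracle(g, grid, 3e4)
  expect_true(all(mc >= 0 & mc <= 1))

  # mirror pixel/LOR pairs agree within binomial error
  n <- g$n_crystals_per_panel
  p1 <- mc[1 + 12 * 5, 2 * n + 4 + 1]           # pixel (1,6), LOR (2,4)
  p2 <- mc[12 + 12 * 5, (n - 3) * n + (n - 5) + 1]  # mirrored
  se <- sqrt(p1 * (1 - p1) / 3e4 + p2 * (1 - p2) / 3e4)
  expect_lt(abs(p1 - p2), 5 * se + 1e-12)

  # row sums approximate the per-pixel geometric acceptance
  cache <- build_system_cache(g, grid)
  gs <- geometric_sensitivity(cache)
  rs <- rowSums(mc)
  expect_equal(rs, as.numeric(gs$values), tolerance = 0.05)

  expect_error(mc_system_matrix_oracle(panel_geometry(280, 300, 2),
                                       grid, 10), "too large")
})
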