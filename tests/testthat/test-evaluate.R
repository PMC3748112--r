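test_that("intensity profiles interpolate correctly", {
  g <- small_geom()
  grid <- fov_grid(g, 1)
  flat <- grid
  flat$values[] <- 3.7
  p <- intensity_profile(flat, c(-5, -10), c(5, 10))
  expect_true(all(abs(p$intensity - 3.7) < 1e-12))

  # full width at half plateau across a rasterized disc of the true phantom
  ph <- nema_iq_phantom()
  les <- ph$lesions[ph$lesions$name == "hot_22mm", ]
  pr <- intensity_profile(ph$image, c(les$x - 30, les$y),
                          c(les$x + 30, les$y), step = 0.25)
  w <- panelpet:::profile_fwhm(pr$distance, pr$intensity - 5.3)
  expect_lt(abs(as.numeric(w) - 22), 2)

  expect_error(intensity_profile(flat, c(0, 0), c(0, 0)), "degenerate")
  empty <- intensity_profile(flat, c(500, 500), c(600, 600))
  expect_equal(nrow(empty), 0L)
})

test_that("CRC formulas evaluate the defining ratios", {
  expect_equal(crc_hot(4, 1, 4), 1)
  expect_equal(crc_hot(1, 1, 4), 0)
  expect_equal(crc_hot(2.5, 1, 4), 0.5)
  expect_error(crc_hot(2, 1, 1), "undefined")
  expect_error(crc_hot(2, 0, 4), "positive")

  expect_equal(crc_cold(0, 2), 1)
  expect_equal(crc_cold(2, 2), 0)
  expect_equal(crc_cold(0.5, 2), 0.75)
})

test_that("CRC is scale invariant and exact on the true phantom", {
  ph <- nema_iq_phantom()
  tab <- crc_table(ph$image, ph)
  expect_true(all(abs(tab$crc - 1) < 1e-12))

  scaled <- ph$image
  scaled$values <- scaled$values * 17.3
  tab2 <- crc_table(scaled, ph)
  expect_equal(tab2$crc, tab$crc)
})

test_that("background mask geometry", {
  ph <- nema_iq_phantom()
  m <- background_mask(ph)
  expect_lt(abs(sum(m) - pi * 900) / (pi * 900), 0.05)
  lesions <- Reduce(`|`, ph$regions[ph$lesions$name])
  expect_true(!any(m & lesions))
  expect_error(background_mask(ph, diameter = 10, center = c(500, 500)),
               "body")
})

test_that("elongation ratio measures blob anisotropy", {
  grid <- pet_image(matrix(0, 120, 120), 1, c(-60, -60))
  cc <- pixel_centers(grid)
  gx <- outer(cc$x, rep(1, 120))
  gy <- outer(rep(1, 120), cc$y)

  iso <- grid
  iso$values <- exp(-(gx^2 + gy^2) / (2 * 6^2))
  r_iso <- elongation_ratio(iso, c(0, 0), 35, smooth_fwhm = 0,
                            baseline = "zero")
  expect_equal(r_iso$ratio, 1, tolerance = 0.05)

  stretched <- grid
  stretched$values <- exp(-(gx^2 / (2 * 6^2) + gy^2 / (2 * 12^2)))
  r_st <- elongation_ratio(stretched, c(0, 0), 50, smooth_fwhm = 0,
                           baseline = "zero")
  expect_equal(r_st$ratio, 2, tolerance = 0.1)

  # true (unreconstructed) phantom lesion is isotropic up to rasterization
  ph <- nema_iq_phantom()
  les <- ph$lesions[4, ]
  r_true <- elongation_ratio(ph$image, c(les$x, les$y), 18, smooth_fwhm = 0)
  expect_equal(r_true$ratio, 1, tolerance = 0.1)
})

test_that("gaussian smoothing preserves flat regions and total mass shape", {
  grid <- pet_image(matrix(5, 40, 40), 2, c(-40, -40))
  sm <- smooth_image(grid, 6)
  expect_true(all(abs(sm$values - 5) < 1e-9))
  expect_identical(smooth_image(grid, 0), grid)
})

test_that("CRC versus iteration reports convergence", {
  ph <- nema_iq_phantom()
  snap <- lapply(1:4, function(i) ph$image)
  fake <- structure(list(snapshots = snap,
                         config = list(timing_fwhm = 300)),
                    class = "pet_recon")
  out <- crc_vs_iteration(fake, ph)
  expect_equal(nrow(out$table), 24L)
  expect_true(all(out$convergence == 2L))
  # flat curves: CRC identical across iterations
  sp <- split(out$table$crc, out$table$lesion)
  expect_true(all(vapply(sp, function(x) diff(range(x)) == 0, logical(1))))

  no_snap <- structure(list(snapshots = NULL, config = list()),
                       class = "pet_recon")
  expect_error(crc_vs_iteration(no_snap, ph), "snapshots")
})
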