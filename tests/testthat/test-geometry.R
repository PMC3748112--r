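test_that("panel geometry construction and validation", {
  g <- panel_geometry(280, 300, 2)
  expect_equal(g$n_crystals_per_panel, 140L)
  expect_error(panel_geometry(280, 300, 3), "integer multiple")
  expect_error(panel_geometry(-280, 300, 2), "positive")
  expect_error(panel_geometry(280, 0, 2), "positive")

  g2 <- panel_geometry(4, 10, 2)
  expect_equal(g2$n_crystals_per_panel, 2L)
  expect_equal(crystal_centers(g2), c(-1, 1))
})

test_that("LOR enumeration is a deterministic bijection with correct endpoints", {
  g2 <- panel_geometry(4, 10, 2)
  lors <- enumerate_lors(g2)
  expect_equal(nrow(lors), 4L)
  expect_equal(lors$crystal_a, c(0L, 0L, 1L, 1L))
  expect_equal(lors$crystal_b, c(0L, 1L, 0L, 1L))
  expect_true(all(lors$ay == 5) && all(lors$by == -5))

  g <- panel_geometry()
  lors <- enumerate_lors(g)
  expect_equal(nrow(lors), 19600L)
  expect_equal(anyDuplicated(lors[, c("crystal_a", "crystal_b")]), 0L)
  expect_true(all(lors$ay == g$panel_separation / 2))
})

test_that("TOF position: zero case, magnitude, sign convention", {
  g <- panel_geometry()
  ep <- lor_endpoints(g, 10L, 25L)
  mid <- (ep$a + ep$b) / 2
  expect_equal(as.numeric(tof_position(g, 10L, 25L, 0)), as.numeric(mid))

  # vertical LOR, separation 300: +667.1 ps -> 100.0 mm toward the bottom
  p <- tof_position(g, 69L, 69L, 667.1)
  expect_equal(as.numeric(p[1, "y"] - 0), -100.0, tolerance = 1e-4)

  # annihilation nearer the top crystal: t_top smaller, delta_t < 0,
  # displaced toward the top panel
  p_neg <- tof_position(g, 69L, 69L, -300)
  expect_gt(p_neg[1, "y"], 0)
})

test_that("TOF position round trip and antisymmetry", {
  g <- panel_geometry()
  set.seed(42)
  cvel <- 0.299792458
  for (rep in 1:50) {
    a <- sample(0:139, 1)
    b <- sample(0:139, 1)
    ep <- lor_endpoints(g, a, b)
    t <- runif(1)
    P <- ep$a + t * (ep$b - ep$a)
    dt_true <- (sqrt(sum((P - ep$a)^2)) - sqrt(sum((P - ep$b)^2))) / cvel
    expect_lt(max(abs(tof_position(g, a, b, dt_true) - P)), 1e-9)
    # mirror about the midpoint
    mid <- (ep$a + ep$b) / 2
    p1 <- tof_position(g, a, b, dt_true)
    p2 <- tof_position(g, a, b, -dt_true)
    expect_lt(max(abs((p1 + p2) / 2 - mid)), 1e-9)
  }
})

test_that("ROI window predicate uses half-open max edges", {
  roi <- roi_window(-10, 10, -20, 20)
  expect_true(point_in_roi(roi, c(0, 0)))
  expect_false(point_in_roi(roi, c(10, 0)))      # on x_max edge
  expect_true(point_in_roi(roi, c(-10, -20)))    # closed min corner
  expect_equal(point_in_roi(roi, rbind(c(0, 0), c(11, 0), c(0, 20))),
               c(TRUE, FALSE, FALSE))
})

test_that("ROI window validation", {
  expect_error(roi_window(5, -5, 0, 1), "x_min < x_max")
  g <- panel_geometry()
  expect_error(roi_window(-200, 0, 0, 10, geom = g), "inside the field of view")
  expect_silent(roi_window(-140, 140, -150, 150, geom = g))
})

test_that("FOV window matches the panel extent", {
  g <- panel_geometry()
  fov <- fov_window(g)
  expect_equal(c(fov$x_min, fov$x_max, fov$y_min, fov$y_max),
               c(-140, 140, -150, 150))
})
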