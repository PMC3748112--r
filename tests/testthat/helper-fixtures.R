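# Shared fixtures: small instances keep unit tests fast; the full study
# geometry appears only in the acceptance tests (memoized in
# helper-acceptance.R).

# 8-crystal panels, 2 mm pitch, 60 mm separation
small_geom <- function() panel_geometry(16, 60, 2)

# 32-crystal panels for mid-size reconstructions
mid_geom <- function() panel_geometry(64, 80, 2)

# uniform disc source centred in a small FOV
disc_activity <- function(geom, pixel_size = 2, diameter = 24,
                          center = c(0, 0)) {
  grid <- fov_grid(geom, pixel_size)
  grid$values[rasterize_disc(grid, center, diameter)] <- 1
  grid
}

# quick list-mode acquisition from a disc source
quick_listmode <- function(geom = mid_geom(), n_decays = 2e4,
                           timing_fwhm = 200, seed = 1, pixel_size = 2,
                           diameter = 30) {
  act <- disc_activity(geom, pixel_size, diameter)
  simulate_listmode(act, geom,
                    acquisition_config(n_decays, timing_fwhm, seed = seed))
}

# hand-built list-mode container for unit tests
manual_listmode <- function(geom, crystal_a, crystal_b, delta_t) {
  n <- length(crystal_a)
  ev <- data.frame(seq = seq_len(n), crystal_a = crystal_a,
                   crystal_b = crystal_b, delta_t = delta_t,
                   energy_a = rep(511, n), energy_b = rep(511, n),
                   true_x = rep(0, n), true_y = rep(0, n))
  panelpet:::new_listmode(ev, list(
    geometry = unclass(geom)[c("panel_length", "panel_separation",
                               "crystal_pitch")],
    timing_fwhm = 0, energy_fwhm_fraction = 0, energy_window = c(400, 600),
    coincidence_window = 6000, n_decays_simulated = n))
}

# Independent dense-matrix EM: explicitly materializes p(j; i, t) for every
# event from geometric_weights() and dnorm(), then iterates the EM update
# with plain R matrix algebra. Oracle for the list-mode C++ path.
dense_em <- function(data, geom, grid, kernel, sens, n_iter, n_quad = 12) {
  g <- panelpet:::as_grid(grid)
  ev <- data$events
  npix <- g$nx * g$ny
  P <- matrix(0, nrow(ev), npix)
  for (k in seq_len(nrow(ev))) {
    w <- geometric_weights(geom, ev$crystal_a[k], ev$crystal_b[k], grid,
                           n_quad = n_quad)
    ut <- 0.299792458 * ev$delta_t[k] / 2
    gk <- dnorm(w$u - ut, sd = kernel$sigma_x)
    P[k, w$ix + g$nx * (w$iy - 1L)] <- w$weight * gk
  }
  s <- as.numeric(sens$values)
  lambda <- as.numeric(s > 0)
  traj <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    denom <- as.numeric(P %*% lambda)
    ratio <- crossprod(P, 1 / denom)
    lambda <- ifelse(s > 0, lambda * as.numeric(ratio) / s, 0)
    traj[[it]] <- lambda
  }
  traj
}
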