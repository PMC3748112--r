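#' Acquisition configuration
#'
#' @param n_decays Number of annihilations to simulate (> 0).
#' @param timing_fwhm Timing resolution FWHM in ps (>= 0; 0 = perfect timing).
#' @param energy_fwhm_fraction Fractional energy resolution at 511 keV
#'   (default 0.13; 0 = perfect energy).
#' @param energy_window Length-2 numeric, accepted photon energy range in keV
#'   (default c(400, 600)).
#' @param coincidence_window Coincidence window in ps: events with
#'   `|delta_t| > coincidence_window` are rejected (default 6000, i.e. 6 ns).
#' @param seed Integer RNG seed recorded in the metadata; `NULL` leaves the
#'   current RNG state untouched.
#' @return List of class `acquisition_config`.
#' @export
acquisition_config <- function(n_decays, timing_fwhm,
                               energy_fwhm_fraction = 0.13,
                               energy_window = c(400, 600),
                               coincidence_window = 6000, seed = NULL) {
  if (n_decays <= 0) stop("n_decays must be positive")
  if (timing_fwhm < 0 || energy_fwhm_fraction < 0)
    stop("resolutions must be non-negative")
  if (length(energy_window) != 2 || energy_window[1] >= energy_window[2])
    stop("energy_window must be an increasing pair")
  if (coincidence_window <= 0) stop("coincidence_window must be positive")
  structure(list(n_decays = as.integer(n_decays), timing_fwhm = timing_fwhm,
                 energy_fwhm_fraction = energy_fwhm_fraction,
                 energy_window = energy_window,
                 coincidence_window = coincidence_window, seed = seed),
            class = "acquisition_config")
}

#' Sample annihilation positions from an activity image
#'
#' Pixels are chosen with probability proportional to their activity value;
#' the position is uniform within the chosen pixel. Activity values act only
#' as relative sampling weights; the absolute count scale is set by `n`.
#'
#' @param activity A [pet_image()] with at least one positive pixel.
#' @param n Number of positions to draw.
#' @return An n x 2 matrix of (x, y) positions in mm.
#' @export
sample_decays <- function(activity, n) {
  v <- activity$values
  if (all(v <= 0)) stop("activity image has no positive pixel (empty source)")
  if (n <= 0) stop("n must be positive")
  g <- as_grid(activity)
  pick <- sample.int(length(v), n, replace = TRUE, prob = as.numeric(v))
  ix <- (pick - 1L) %% g$nx
  iy <- (pick - 1L) %/% g$nx
  cbind(x = g$x0 + (ix + runif(n)) * g$px,
        y = g$y0 + (iy + runif(n)) * g$px)
}

#' Trace back-to-back photons from annihilation points to the panels
#'
#' Each annihilation emits two exactly anti-parallel photons in the transverse
#' plane along the given angle (a line through the point). If both rays strike
#' a panel face within the panel extent the struck crystals and the true
#' arrival-time difference are returned. Detection position is the
#' intersection with the panel face; the true time difference is
#' `(L_top - L_bottom) / c` with L the path lengths to the faces.
#'
#' @param geom A [panel_geometry()].
#' @param position n x 2 matrix of annihilation points (mm), strictly between
#'   the panel faces.
#' @param angle Emission angles in radians, in `[0, pi)` (the direction of the
#'   upward-going photon).
#' @return Data frame with `crystal_a`, `crystal_b` (0-based; NA where no
#'   coincidence) and `true_delta_t` (ps).
#' @export
trace_coincidence <- function(geom, position, angle) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 2)
  H <- geom$panel_separation / 2
  if (any(abs(position[, 2]) >= H))
    stop("annihilation position outside the field of view")
  L2 <- geom$panel_length / 2
  s <- sin(angle)
  ok <- s > 0
  cot <- ifelse(ok, cos(angle) / s, NA_real_)
  xt <- position[, 1] + (H - position[, 2]) * cot
  xb <- position[, 1] - (H + position[, 2]) * cot
  hit <- ok & xt >= -L2 & xt < L2 & xb >= -L2 & xb < L2
  ka <- ifelse(hit, floor((xt + L2) / geom$crystal_pitch), NA_real_)
  kb <- ifelse(hit, floor((xb + L2) / geom$crystal_pitch), NA_real_)
  la <- (H - position[, 2]) / s
  lb <- (H + position[, 2]) / s
  dt <- ifelse(hit, (la - lb) / .C_MM_PER_PS, NA_real_)
  data.frame(crystal_a = as.integer(ka), crystal_b = as.integer(kb),
             true_delta_t = dt)
}

#' Apply Gaussian timing and energy blur to true event quantities
#'
#' Measured `delta_t` is the true difference plus Gaussian noise with
#' `sigma_t = timing_fwhm / (2 sqrt(2 log 2))`; each photon energy is 511 keV
#' plus Gaussian noise with `sigma_E = energy_fwhm_fraction * 511 / (2 sqrt(2
#' log 2))`.
#'
#' @param true_delta_t True time differences (ps).
#' @param timing_fwhm Timing FWHM (ps).
#' @param energy_fwhm_fraction Fractional energy FWHM at 511 keV.
#' @return Data frame `delta_t`, `energy_a`, `energy_b`.
#' @export
blur_events <- function(true_delta_t, timing_fwhm, energy_fwhm_fraction) {
  n <- length(true_delta_t)
  sig_t <- timing_fwhm * .FWHM_TO_SIGMA
  sig_e <- energy_fwhm_fraction * 511 * .FWHM_TO_SIGMA
  data.frame(
    delta_t = true_delta_t + (if (sig_t > 0) rnorm(n, 0, sig_t) else 0),
    energy_a = 511 + (if (sig_e > 0) rnorm(n, 0, sig_e) else 0),
    energy_b = 511 + (if (sig_e > 0) rnorm(n, 0, sig_e) else 0))
}

#' Energy and coincidence window acceptance
#'
#' @param delta_t Measured time differences (ps).
#' @param energy_a,energy_b Measured photon energies (keV).
#' @param energy_window Accepted energy range, keV (closed interval).
#' @param coincidence_window Max `|delta_t|`, ps.
#' @return Logical acceptance vector.
#' @export
apply_windows <- function(delta_t, energy_a, energy_b,
                          energy_window = c(400, 600),
                          coincidence_window = 6000) {
  energy_a >= energy_window[1] & energy_a <= energy_window[2] &
    energy_b >= energy_window[1] & energy_b <= energy_window[2] &
    abs(delta_t) <= coincidence_window
}

# internal constructor for list-mode containers
new_listmode <- function(events, meta) {
  structure(list(events = events, meta = meta), class = "listmode")
}

#' Monte Carlo list-mode acquisition
#'
#' Samples `cfg$n_decays` annihilations from the activity image, traces
#' back-to-back photon pairs to the panels (emission angle uniform on
#' `[0, pi)`), blurs timing and energies, applies the energy and coincidence
#' windows, and returns the accepted coincidences in simulation order.
#' Positron range, acollinearity, attenuation and scatter are not modelled:
#' every recorded coincidence is a true coincidence. Fully reproducible from
#' the seed.
#'
#' @param activity A [pet_image()] of emission intensities.
#' @param geom A [panel_geometry()].
#' @param cfg An [acquisition_config()].
#' @return Object of class `listmode`: `events` is a data frame with columns
#'   `seq`, `crystal_a`, `crystal_b`, `delta_t` (ps), `energy_a`, `energy_b`
#'   (keV), `true_x`, `true_y` (mm, retained for validation); `meta` records
#'   the acquisition parameters, geometry and seed.
#' @export
simulate_listmode <- function(activity, geom, cfg) {
  stopifnot(inherits(cfg, "acquisition_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pos <- sample_decays(activity, cfg$n_decays)
  ang <- runif(cfg$n_decays, 0, pi)
  tr <- trace_coincidence(geom, pos, ang)
  hit <- !is.na(tr$crystal_a)
  bl <- blur_events(tr$true_delta_t[hit], cfg$timing_fwhm,
                    cfg$energy_fwhm_fraction)
  acc <- apply_windows(bl$delta_t, bl$energy_a, bl$energy_b,
                       cfg$energy_window, cfg$coincidence_window)
  events <- data.frame(
    seq = seq_len(sum(acc)),
    crystal_a = tr$crystal_a[hit][acc], crystal_b = tr$crystal_b[hit][acc],
    delta_t = bl$delta_t[acc], energy_a = bl$energy_a[acc],
    energy_b = bl$energy_b[acc],
    true_x = pos[hit, 1][acc], true_y = pos[hit, 2][acc])
  meta <- list(geometry = unclass(geom)[c("panel_length", "panel_separation",
                                          "crystal_pitch")],
               timing_fwhm = cfg$timing_fwhm,
               energy_fwhm_fraction = cfg$energy_fwhm_fraction,
               energy_window = cfg$energy_window,
               coincidence_window = cfg$coincidence_window,
               rng_seed = cfg$seed, n_decays_simulated = cfg$n_decays,
               n_traced = sum(hit), n_accepted = sum(acc))
  new_listmode(events, meta)
}

#' Re-blur a perfect-resolution acquisition
#'
#' The study's resampling shortcut: simulate once with perfect timing and
#' energy resolution, then impose any target resolution afterwards. Gaussian
#' blur is added to the stored (perfect) time differences and energies and
#' the acquisition windows are re-applied; the result is distributionally
#' identical to simulating directly at the target resolution.
#'
#' @param data A `listmode` acquired with `timing_fwhm = 0` and
#'   `energy_fwhm_fraction = 0`.
#' @param timing_fwhm Target timing FWHM (ps).
#' @param energy_fwhm_fraction Target fractional energy resolution
#'   (default 0.13).
#' @param seed Optional RNG seed for the blur draws.
#' @return A new `listmode` with blurred events, windows re-applied and
#'   events renumbered chronologically.
#' @export
reblur_listmode <- function(data, timing_fwhm, energy_fwhm_fraction = 0.13,
                            seed = NULL) {
  stopifnot(inherits(data, "listmode"))
  if (data$meta$timing_fwhm != 0 || data$meta$energy_fwhm_fraction != 0)
    stop("reblur requires a perfect-resolution (FWHM = 0) acquisition")
  if (!is.null(seed)) set.seed(seed)
  ev <- data$events
  bl <- blur_events(ev$delta_t, timing_fwhm, energy_fwhm_fraction)
  acc <- apply_windows(bl$delta_t, bl$energy_a, bl$energy_b,
                       data$meta$energy_window, data$meta$coincidence_window)
  events <- data.frame(
    seq = seq_len(sum(acc)),
    crystal_a = ev$crystal_a[acc], crystal_b = ev$crystal_b[acc],
    delta_t = bl$delta_t[acc], energy_a = bl$energy_a[acc],
    energy_b = bl$energy_b[acc], true_x = ev$true_x[acc],
    true_y = ev$true_y[acc])
  meta <- data$meta
  meta$timing_fwhm <- timing_fwhm
  meta$energy_fwhm_fraction <- energy_fwhm_fraction
  meta$rng_seed <- seed
  meta$n_accepted <- sum(acc)
  meta$reblurred_from <- data$meta$n_accepted
  new_listmode(events, meta)
}

#' Number of events in a list-mode dataset
#' @param data A `listmode`.
#' @return Integer event count.
#' @export
n_events <- function(data) nrow(data$events)

#' @export
print.listmode <- function(x, ...) {
  cat(sprintf("List-mode data: %d coincidences (%s decays simulated)\n",
              nrow(x$events),
              format(x$meta$n_decays_simulated, big.mark = ",")))
  cat(sprintf("  timing FWHM %g ps, energy res %g@511 keV, windows %g-%g keV, |dt| <= %g ps\n",
              x$meta$timing_fwhm, x$meta$energy_fwhm_fraction,
              x$meta$energy_window[1], x$meta$energy_window[2],
              x$meta$coincidence_window))
  if (!is.null(x$meta$roi_filter))
    cat(sprintf("  ROI-filtered: kept %d of %d events\n",
                x$meta$roi_filter$kept, x$meta$roi_filter$total))
  invisible(x)
}

#' @export
summary.listmode <- function(object, ...) {
  ev <- object$events
  cat(sprintf("%d events; delta_t in [%.1f, %.1f] ps (sd %.1f)\n",
              nrow(ev), min(ev$delta_t), max(ev$delta_t),
              stats::sd(ev$delta_t)))
  invisible(object)
}
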