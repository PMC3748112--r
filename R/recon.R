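#' TOF-based ROI event discrimination
#'
#' Keeps exactly the events whose TOF-implied annihilation position — the LOR
#' midpoint displaced by c*delta_t/2 along the LOR using the *measured*
#' (blurred) time difference — lies inside the ROI. The measured difference is
#' the only physically available quantity, so some in-ROI annihilations are
#' lost and some out-of-ROI ones kept; the matching truncated sensitivity
#' accounts for this consistently.
#'
#' @param data A `listmode` dataset.
#' @param geom A [panel_geometry()] (defaults to the geometry stored in the
#'   acquisition metadata).
#' @param roi An [roi_window()].
#' @return A `listmode` with the kept events (order preserved) and the filter
#'   recorded in the metadata.
#' @export
filter_events_roi <- function(data, geom = NULL, roi) {
  stopifnot(inherits(data, "listmode"), inherits(roi, "roi_window"))
  if (is.null(geom)) geom <- geometry_from_meta(data)
  ev <- data$events
  keep <- if (nrow(ev) == 0) logical(0) else
    point_in_roi(roi, tof_position(geom, ev$crystal_a, ev$crystal_b,
                                   ev$delta_t))
  out <- data
  out$events <- ev[keep, , drop = FALSE]
  out$meta$roi_filter <- list(roi = unclass(roi), kept = sum(keep),
                              total = nrow(ev))
  out
}

geometry_from_meta <- function(data) {
  gm <- data$meta$geometry
  if (is.null(gm)) stop("list-mode metadata carries no geometry")
  panel_geometry(gm$panel_length, gm$panel_separation, gm$crystal_pitch)
}

#' Chronological ordered-subset partition
#'
#' Splits the event stream into `n_subsets` contiguous chronological blocks of
#' near-equal size (sizes differ by at most one; the remainder goes to the
#' leading blocks).
#'
#' @param data A `listmode` dataset (or an integer event count).
#' @param n_subsets Number of subsets (>= 1).
#' @return List of integer vectors of event row indices, in chronological
#'   block order.
#' @export
partition_subsets <- function(data, n_subsets) {
  k <- if (inherits(data, "listmode")) nrow(data$events) else as.integer(data)
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  if (k < n_subsets)
    stop(sprintf("only %d events for %d subsets; use fewer subsets", k,
                 n_subsets))
  sizes <- rep(k %/% n_subsets, n_subsets)
  rem <- k %% n_subsets
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

# 0-based subset boundaries for the C++ driver
subset_bounds <- function(k, n_subsets) {
  sizes <- rep(k %/% n_subsets, n_subsets)
  rem <- k %% n_subsets
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  as.integer(c(0L, cumsum(sizes)))
}

# events -> (0-based LOR index, TOF coordinate u_t in mm)
event_arrays <- function(data, geom) {
  ev <- data$events
  n <- geom$n_crystals_per_panel
  if (nrow(ev) > 0 &&
      (min(ev$crystal_a, ev$crystal_b) < 0 ||
       max(ev$crystal_a, ev$crystal_b) >= n))
    stop("event crystal index outside the panel")
  list(lor = as.integer(ev$crystal_a * n + ev$crystal_b),
       ut = .C_MM_PER_PS * ev$delta_t / 2)
}

#' List-mode OSEM reconstruction
#'
#' Fits the emission image by list-mode ordered-subset expectation
#' maximization with TOF weighting. The update for one chronological subset B
#' is
#' \deqn{\lambda_j \leftarrow \frac{\lambda_j}{s_j} \sum_{k \in B}
#'   \frac{p(j; i_k, t_k)}{\sum_{j'} p(j'; i_k, t_k)\,\lambda_{j'}}}
#' with `p(j; i, t) = p_geom(j; i) h_TOF(u_j - c t/2)` the factorized system
#' model and `s_j` the sensitivity. In the windowed mode (an `roi` is given)
#' events are first discriminated by their TOF position
#' ([filter_events_roi()]) and `s` is the matching ROI-truncated sensitivity;
#' the conventional mode is the same algorithm with the ROI set to the full
#' FOV rectangle. All in-FOV pixels start from a uniform positive value;
#' pixels with zero sensitivity stay exactly zero. The result is deterministic
#' given the data and configuration.
#'
#' @param data A `listmode` dataset.
#' @param geom A [panel_geometry()]; defaults to the acquisition metadata.
#' @param roi An [roi_window()] for windowed reconstruction, or NULL for the
#'   conventional mode (ROI = full FOV).
#' @param n_iterations Full iterations (default 10).
#' @param n_subsets Ordered subsets per iteration (default 16).
#' @param pixel_size Reconstruction pixel size in mm (default 1); ignored if
#'   `grid` is given.
#' @param initial_value Uniform initial intensity (> 0, default 1).
#' @param timing_fwhm Timing resolution FWHM (ps) assumed by the TOF kernel;
#'   defaults to the acquisition metadata.
#' @param time_bin_width TOF bin width for the sensitivity summation, ps.
#' @param grid Optional [pet_image()]/grid spec for the reconstruction raster
#'   (default: the FOV at `pixel_size`).
#' @param cache Optional prebuilt [build_system_cache()] for this geometry and
#'   grid (reused across reconstructions in sweeps).
#' @param snapshots If TRUE, keep the image after every full iteration.
#' @param n_quad Gauss-Legendre order of the geometric model.
#' @param trunc_nsig Gaussian TOF factors are evaluated within this many
#'   sigma of the TOF position (default 10; contributions beyond are below
#'   1e-21 of the mode).
#' @return Object of class `pet_recon` with elements `image` (full-grid
#'   [pet_image()]), `roi_image` (cropped to the ROI), `roi`, `method`,
#'   `sensitivity`, `counts` (events total/used/skipped), `snapshots`
#'   (list of [pet_image()] or NULL), and `config`.
#' @seealso [reconstruct_osem()], [reconstruct_windowed()], [loglikelihood()]
#' @export
reconstruct <- function(data, geom = NULL, roi = NULL, n_iterations = 10,
                        n_subsets = 16, pixel_size = 1, initial_value = 1,
                        timing_fwhm = NULL, time_bin_width = 25, grid = NULL,
                        cache = NULL, snapshots = FALSE, n_quad = 12,
                        trunc_nsig = 10) {
  stopifnot(inherits(data, "listmode"))
  if (n_iterations < 1 || n_subsets < 1) stop("iterations and subsets must be >= 1")
  if (initial_value <= 0) stop("initial_value must be positive")
  if (is.null(geom)) geom <- geometry_from_meta(data)
  method <- if (is.null(roi)) "conventional" else "windowed"
  if (is.null(roi)) roi <- fov_window(geom)
  if (is.null(timing_fwhm)) timing_fwhm <- data$meta$timing_fwhm
  if (is.null(timing_fwhm)) stop("timing_fwhm not given and absent from metadata")
  kernel <- tof_kernel(timing_fwhm, time_bin_width,
                       data$meta$coincidence_window %||% 6000)
  if (is.null(grid)) grid <- fov_grid(geom, pixel_size)
  g <- as_grid(grid)
  if (is.null(cache)) cache <- build_system_cache(geom, grid, n_quad)

  total <- nrow(data$events)
  fdata <- filter_events_roi(data, geom, roi)
  used <- nrow(fdata$events)
  if (used == 0) stop("no events remain after ROI discrimination")

  sens <- .sensitivity(cache, kernel, roi,
                       if (method == "windowed") "windowed" else "full")
  ea <- event_arrays(fdata, geom)
  lambda0 <- as.numeric(initial_value * (sens$values > 0))
  fit <- cpp_osem(cache, ea$lor, ea$ut, as.numeric(sens$values), lambda0,
                  n_iterations, subset_bounds(used, n_subsets),
                  kernel$sigma_x, trunc_nsig, g$px, snapshots)

  img <- pet_image(matrix(fit$image, g$nx, g$ny), g$px, c(g$x0, g$y0),
                   units = "reconstructed intensity")
  snaps <- NULL
  if (snapshots) {
    snaps <- lapply(seq_len(n_iterations), function(i)
      pet_image(matrix(fit$snapshots[, i], g$nx, g$ny), g$px, c(g$x0, g$y0),
                units = "reconstructed intensity"))
  }
  structure(list(image = img, roi_image = crop_image(img, roi), roi = roi,
                 method = method, sensitivity = sens,
                 counts = list(total = total, used = used,
                               skipped = fit$skipped),
                 snapshots = snaps, kernel = kernel,
                 config = list(n_iterations = n_iterations,
                               n_subsets = n_subsets,
                               initial_value = initial_value,
                               timing_fwhm = timing_fwhm,
                               time_bin_width = time_bin_width,
                               n_quad = n_quad, trunc_nsig = trunc_nsig,
                               pixel_size = g$px),
                 geom = geom),
            class = "pet_recon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conventional list-mode TOF-OSEM
#'
#' The windowed algorithm with the ROI fixed to the full FOV rectangle: the
#' scanner's native operating mode.
#'
#' @inheritParams reconstruct
#' @param ... Passed to [reconstruct()].
#' @return A `pet_recon`.
#' @export
reconstruct_osem <- function(data, ...) {
  args <- list(...)
  if (!is.null(args$roi)) stop("use reconstruct_windowed() for an ROI")
  reconstruct(data, roi = NULL, ...)
}

#' Windowed (ROI) list-mode TOF-OSEM
#'
#' @inheritParams reconstruct
#' @param ... Passed to [reconstruct()].
#' @return A `pet_recon`.
#' @export
reconstruct_windowed <- function(data, roi, ...) {
  stopifnot(inherits(roi, "roi_window"))
  reconstruct(data, roi = roi, ...)
}

#' One list-mode EM sub-iteration
#'
#' Applies the EM update for a single block of events to an image, using the
#' supplied sensitivity. Exposed for algorithm-level checks (count
#' preservation, symmetry, oracle comparisons).
#'
#' @param image A [pet_image()] (current estimate, >= 0).
#' @param data A `listmode` block (all its events are used).
#' @param geom A [panel_geometry()].
#' @param kernel A [tof_kernel()].
#' @param sensitivity A `sensitivity_image` on the same grid.
#' @param cache Optional prebuilt system cache.
#' @param trunc_nsig Gaussian truncation (default 10 sigma).
#' @return List: `image` (updated [pet_image()]), `skipped` (events with zero
#'   forward projection, skipped with a warning).
#' @export
em_update <- function(image, data, geom, kernel, sensitivity, cache = NULL,
                      trunc_nsig = 10) {
  if (nrow(data$events) == 0) stop("empty event block")
  if (all(image$values == 0)) stop("degenerate all-zero image state")
  g <- as_grid(image)
  if (is.null(cache)) cache <- build_system_cache(geom, image)
  ea <- event_arrays(data, geom)
  r <- cpp_em_block(cache, ea$lor, ea$ut, as.numeric(sensitivity$values),
                    as.numeric(image$values), kernel$sigma_x, trunc_nsig,
                    g$px)
  if (r$skipped > 0)
    warning(sprintf("%d event(s) with zero forward projection skipped",
                    r$skipped))
  list(image = pet_image(matrix(pmax(r$image, 0), g$nx, g$ny), g$px,
                         c(g$x0, g$y0), units = image$units),
       skipped = r$skipped)
}

#' Poisson list-mode log-likelihood
#'
#' `sum_k log(sum_j p(j; i_k, t_k) lambda_j) - sum_j s_j lambda_j`. Returns
#' -Inf (with the offending event index in an attribute) if any event has a
#' zero forward projection.
#'
#' @inheritParams em_update
#' @return Numeric log-likelihood, possibly `-Inf` with attribute
#'   `first_zero_event`.
#' @export
loglikelihood <- function(image, data, geom, kernel, sensitivity,
                          cache = NULL, trunc_nsig = 10) {
  g <- as_grid(image)
  if (is.null(cache)) cache <- build_system_cache(geom, image)
  ea <- event_arrays(data, geom)
  r <- cpp_loglik(cache, ea$lor, ea$ut, as.numeric(sensitivity$values),
                  as.numeric(image$values), kernel$sigma_x, trunc_nsig, g$px)
  ll <- r$loglik
  if (r$first_zero_event > 0) attr(ll, "first_zero_event") <- r$first_zero_event
  ll
}

#' @export
print.pet_recon <- function(x, ...) {
  cat(sprintf("List-mode %s OSEM reconstruction\n", x$method))
  cat(sprintf("  %d iterations x %d subsets, TOF FWHM %g ps\n",
              x$config$n_iterations, x$config$n_subsets,
              x$config$timing_fwhm))
  cat(sprintf("  events: %d used of %d (%d skipped in updates)\n",
              x$counts$used, x$counts$total, x$counts$skipped))
  print(x$image)
  invisible(x)
}

#' @export
summary.pet_recon <- function(object, ...) {
  print(object)
  v <- object$roi_image$values
  cat(sprintf("  ROI image: %d x %d pixels, mean %.4g, max %.4g\n",
              nrow(v), ncol(v), mean(v), max(v)))
  invisible(object)
}

#' @export
plot.pet_recon <- function(x, crop = TRUE, ...) {
  img <- if (crop) x$roi_image else x$image
  plot(img, main = sprintf("%s OSEM (%g ps)", x$method,
                           x$config$timing_fwhm), ...)
  if (!crop)
    rect(x$roi$x_min, x$roi$y_min, x$roi$x_max, x$roi$y_max, border = "red",
         lty = 2)
  invisible(x)
}

#' @export
coef.pet_recon <- function(object, ...) object$image$values

#' @export
logLik.pet_recon <- function(object, data = NULL, ...) {
  if (is.null(data))
    stop("supply the list-mode data: logLik(fit, data = ...)")
  fdata <- filter_events_roi(data, object$geom, object$roi)
  ll <- loglikelihood(object$image, fdata, object$geom, object$kernel,
                      object$sensitivity, trunc_nsig = object$config$trunc_nsig)
  structure(as.numeric(ll), df = sum(object$sensitivity$values > 0),
            nobs = nrow(fdata$events), class = "logLik")
}
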