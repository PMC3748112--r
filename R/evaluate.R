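#' Intensity profile along a line segment
#'
#' Bilinear interpolation of the image at equally spaced samples along the
#' segment from `from` to `to`.
#'
#' @param image A [pet_image()].
#' @param from,to Length-2 numeric endpoints, mm.
#' @param step Sample spacing in mm (default half a pixel).
#' @return Data frame `distance` (mm from `from`), `x`, `y`, `intensity`.
#'   Samples outside the grid are dropped; an empty data frame if the segment
#'   misses the grid entirely.
#' @export
intensity_profile <- function(image, from, to, step = image$pixel_size / 2) {
  if (step <= 0) stop("step must be positive")
  len <- sqrt(sum((to - from)^2))
  if (len == 0) stop("degenerate profile: from == to")
  d <- seq(0, len, by = step)
  xs <- from[1] + d / len * (to[1] - from[1])
  ys <- from[2] + d / len * (to[2] - from[2])
  cc <- pixel_centers(image)
  inside <- xs >= min(cc$x) & xs <= max(cc$x) & ys >= min(cc$y) &
    ys <= max(cc$y)
  if (!any(inside))
    return(data.frame(distance = numeric(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0)))
  v <- pracma::interp2(cc$x, cc$y, t(image$values), xs[inside], ys[inside],
                       method = "linear")
  data.frame(distance = d[inside], x = xs[inside], y = ys[inside],
             intensity = v)
}

#' Hot-lesion contrast recovery coefficient
#'
#' `CRC_hot = (lesion_mean / background_mean - 1) / (true_ratio - 1)`: 1 means
#' the full true contrast was recovered.
#'
#' @param lesion_mean Mean reconstructed intensity over the lesion region.
#' @param background_mean Mean over the background region (> 0).
#' @param true_hot_ratio True lesion-to-background uptake ratio (> 1).
#' @return Dimensionless CRC.
#' @export
crc_hot <- function(lesion_mean, background_mean, true_hot_ratio) {
  if (any(background_mean <= 0)) stop("background_mean must be positive")
  if (any(true_hot_ratio == 1))
    stop("contrast undefined for true ratio 1")
  (lesion_mean / background_mean - 1) / (true_hot_ratio - 1)
}

#' Cold-lesion contrast recovery coefficient
#'
#' `CRC_cold = 1 - lesion_mean / background_mean`: 1 means a perfectly empty
#' cold lesion.
#'
#' @inheritParams crc_hot
#' @return Dimensionless CRC (<= 1).
#' @export
crc_cold <- function(lesion_mean, background_mean) {
  if (any(background_mean <= 0)) stop("background_mean must be positive")
  1 - lesion_mean / background_mean
}

#' Central background region mask
#'
#' A disc of the given diameter (default 60 mm) at the phantom centre, minus
#' any overlap with lesion masks, used to estimate background counts.
#'
#' @param phantom A `pet_phantom` (from [nema_iq_phantom()]).
#' @param diameter Disc diameter in mm (default 60).
#' @param center Disc centre, mm.
#' @return Logical mask congruent with the phantom grid.
#' @export
background_mask <- function(phantom, diameter = 60, center = c(0, 0)) {
  disc <- rasterize_disc(phantom$image, center, diameter)
  lesion_names <- phantom$lesions$name
  lesions <- Reduce(`|`, phantom$regions[lesion_names])
  if (any(disc & lesions)) {
    warning("background disc overlaps lesion masks; overlapping pixels excluded")
    disc <- disc & !lesions
  }
  disc <- disc & phantom$regions$body
  if (!any(disc)) stop("background disc does not intersect the phantom body")
  disc
}

#' Region means of an image
#'
#' @param image A [pet_image()] (or plain matrix).
#' @param masks Named list of logical masks.
#' @return Named numeric vector of means.
#' @export
region_means <- function(image, masks) {
  v <- if (inherits(image, "pet_image")) image$values else image
  vapply(masks, function(m) mean(v[m]), numeric(1))
}

#' CRC table for a reconstruction of the NEMA-IQ phantom
#'
#' @param image A [pet_image()] (reconstruction on the phantom grid).
#' @param phantom The `pet_phantom` that was imaged.
#' @param bg_mask Background mask (default [background_mask()] of the
#'   phantom).
#' @param iteration,timing_fwhm Optional bookkeeping columns.
#' @return Data frame: lesion, kind, diameter, lesion_mean, background_mean,
#'   crc, iteration, timing_fwhm.
#' @export
crc_table <- function(image, phantom, bg_mask = background_mask(phantom),
                      iteration = NA, timing_fwhm = NA) {
  les <- phantom$lesions
  bgm <- mean((if (inherits(image, "pet_image")) image$values else image)[bg_mask])
  lm <- region_means(image, phantom$regions[les$name])
  crc <- ifelse(les$kind == "hot",
                crc_hot(lm, bgm, phantom$hot_ratio),
                crc_cold(lm, bgm))
  data.frame(lesion = les$name, kind = les$kind, diameter = les$diameter,
             lesion_mean = as.numeric(lm), background_mean = bgm,
             crc = as.numeric(crc), iteration = iteration,
             timing_fwhm = timing_fwhm, row.names = NULL)
}

#' CRC versus iteration
#'
#' Evaluates the contrast recovery of every lesion on each per-iteration
#' snapshot of a reconstruction and reports the first iteration at which the
#' CRC change falls below a convergence threshold.
#'
#' @param recon A `pet_recon` fitted with `snapshots = TRUE`.
#' @param phantom The imaged `pet_phantom`.
#' @param bg_mask Background mask (default the 60 mm central disc).
#' @param convergence_delta Convergence threshold on `|delta CRC|` between
#'   successive iterations (default 0.01).
#' @return List: `table` (CRC per lesion per iteration) and `convergence`
#'   (named vector, first converged iteration per lesion).
#' @export
crc_vs_iteration <- function(recon, phantom,
                             bg_mask = background_mask(phantom),
                             convergence_delta = 0.01) {
  if (is.null(recon$snapshots))
    stop("reconstruction was run without snapshots = TRUE")
  tabs <- lapply(seq_along(recon$snapshots), function(i)
    crc_table(recon$snapshots[[i]], phantom, bg_mask, iteration = i,
              timing_fwhm = recon$config$timing_fwhm))
  tab <- do.call(rbind, tabs)
  conv <- vapply(split(tab, tab$lesion), function(d) {
    d <- d[order(d$iteration), ]
    dd <- abs(diff(d$crc))
    i <- which(dd < convergence_delta)
    if (length(i) == 0) NA_integer_ else as.integer(i[1] + 1L)
  }, integer(1))
  list(table = tab, convergence = conv)
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian convolution with edge renormalization (the kernel mass
#' falling outside the grid is compensated, so flat regions stay flat).
#'
#' @param image A [pet_image()].
#' @param fwhm Smoothing kernel FWHM in mm; 0 returns the image unchanged.
#' @return A smoothed [pet_image()].
#' @export
smooth_image <- function(image, fwhm) {
  if (fwhm <= 0) return(image)
  sigma <- fwhm * .FWHM_TO_SIGMA / image$pixel_size
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {
    # convolve columns of m with k, renormalizing at the edges
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    norm <- numeric(n)
    for (i in seq_along(k)) {
      sh <- i - r - 1L
      src <- seq_len(n) + sh
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[i] * m[src[ok], ]
      norm[ok] <- norm[ok] + k[i]
    }
    out / norm
  }
  sm <- conv1(image$values)
  sm <- t(conv1(t(sm)))
  pet_image(pmax(sm, 0), image$pixel_size, image$origin, units = image$units,
            slice_thickness = image$slice_thickness)
}

# FWHM of a 1D profile about its maximum, by linear interpolation of the
# half-maximum crossings. If the profile never falls below half maximum on a
# side within the sampled range, that side is censored at the range edge (the
# returned width is then a lower bound, flagged by attribute "censored").
profile_fwhm <- function(d, v) {
  if (length(v) < 3 || all(!is.finite(v))) return(NA_real_)
  imax <- which.max(v)
  half <- v[imax] / 2
  censored <- FALSE
  if (imax > 1) {
    below <- which(v[seq_len(imax - 1)] < half)
    if (length(below) > 0) {
      i <- max(below)
      left <- d[i] + (half - v[i]) / (v[i + 1] - v[i]) * (d[i + 1] - d[i])
    } else {
      left <- d[1]
      censored <- TRUE
    }
  } else {
    left <- d[1]
    censored <- TRUE
  }
  if (imax < length(v)) {
    below <- which(v[seq(imax + 1, length(v))] < half) + imax
    if (length(below) > 0) {
      i <- min(below)
      right <- d[i - 1] + (v[i - 1] - half) / (v[i - 1] - v[i]) *
        (d[i] - d[i - 1])
    } else {
      right <- d[length(d)]
      censored <- TRUE
    }
  } else {
    right <- d[length(d)]
    censored <- TRUE
  }
  out <- right - left
  if (censored) attr(out, "censored") <- TRUE
  out
}

#' Lesion elongation ratio
#'
#' Quantifies the vertical stretch of reconstructed lesions characteristic of
#' limited-angle dual-panel imaging: the ratio of the FWHM of the lesion's
#' vertical intensity profile to its horizontal one, both taken through the
#' lesion's intensity centroid within a local window. Values above 1 indicate
#' stretch perpendicular to the panels.
#'
#' @param image A [pet_image()].
#' @param center Approximate lesion centre (x, y), mm.
#' @param halfwidth Half-size of the analysis window, mm; either a scalar or
#'   (half-width in x, half-width in y). Keep the window clear of the bright
#'   ROI-edge artifact band of windowed reconstructions.
#' @param step Profile sampling step, mm.
#' @param baseline Either "min" (subtract the window minimum before the
#'   analysis; appropriate for lesions on a warm background) or "zero".
#' @param smooth_fwhm Gaussian pre-smoothing FWHM in mm (default 3) applied
#'   before profiling, so that the width of the lesion rather than of single
#'   noise speckles is measured; 0 disables.
#' @param band Half-width (mm) of the strip over which each profile is
#'   averaged (default 5); band averaging suppresses residual noise.
#' @return List: `ratio` (vertical FWHM / horizontal FWHM), `fwhm_x`,
#'   `fwhm_y`, `centroid`. A profile that never falls below half maximum
#'   within the window is censored at the window edge (its FWHM is a lower
#'   bound, flagged by attribute `censored`).
#' @export
elongation_ratio <- function(image, center, halfwidth, step = 0.5,
                             baseline = c("min", "zero"), smooth_fwhm = 3,
                             band = 5) {
  baseline <- match.arg(baseline)
  if (length(halfwidth) == 1) halfwidth <- c(halfwidth, halfwidth)
  image <- smooth_image(image, smooth_fwhm)
  cc <- pixel_centers(image)
  ix <- which(abs(cc$x - center[1]) <= halfwidth[1])
  iy <- which(abs(cc$y - center[2]) <= halfwidth[2])
  if (length(ix) < 3 || length(iy) < 3) stop("analysis window too small")
  w <- image$values[ix, iy]
  if (baseline == "min") w <- w - min(w)
  if (sum(w >= max(w) / 2) < 9)
    stop("fewer than 9 pixels above half maximum in the window")
  tot <- sum(w)
  cx <- sum(outer(cc$x[ix], rep(1, length(iy))) * w) / tot
  cy <- sum(outer(rep(1, length(ix)), cc$y[iy]) * w) / tot

  # band-averaged profiles through the centroid: averaging across a strip
  # of width 2*band suppresses residual reconstruction noise that a single
  # interpolated line would pick up
  bx <- ix[abs(cc$x[ix] - cx) <= band]
  by <- iy[abs(cc$y[iy] - cy) <= band]
  if (length(bx) == 0) bx <- ix[which.min(abs(cc$x[ix] - cx))]
  if (length(by) == 0) by <- iy[which.min(abs(cc$y[iy] - cy))]
  horiz <- list(distance = cc$x[ix],
                intensity = rowMeans(image$values[ix, by, drop = FALSE]))
  vert <- list(distance = cc$y[iy],
               intensity = colMeans(image$values[bx, iy, drop = FALSE]))
  base_h <- if (baseline == "min") min(horiz$intensity) else 0
  base_v <- if (baseline == "min") min(vert$intensity) else 0
  fx <- profile_fwhm(horiz$distance, horiz$intensity - base_h)
  fy <- profile_fwhm(vert$distance, vert$intensity - base_v)
  ratio <- as.numeric(fy) / as.numeric(fx)
  if (!is.null(attr(fx, "censored")) || !is.null(attr(fy, "censored")))
    attr(ratio, "censored") <- TRUE
  if (!is.finite(ratio))
    attr(ratio, "reason") <- "profile never crosses half maximum"
  list(ratio = ratio, fwhm_x = fx, fwhm_y = fy, centroid = c(cx, cy))
}

#' Background-corrected lesion centroid
#'
#' Intensity-weighted centroid of the background-subtracted image within a
#' disc around the expected lesion position; used to check for lesion
#' mis-localization. For cold lesions the deficit (background minus image) is
#' weighted instead.
#'
#' @param image A [pet_image()].
#' @param center Expected lesion centre, mm.
#' @param radius Analysis disc radius, mm.
#' @param background Background level to subtract.
#' @param kind "hot" or "cold".
#' @return Length-2 numeric centroid (x, y) in mm.
#' @export
lesion_centroid <- function(image, center, radius, background,
                            kind = c("hot", "cold")) {
  kind <- match.arg(kind)
  disc <- rasterize_disc(image, center, 2 * radius)
  cc <- pixel_centers(image)
  w <- image$values - background
  if (kind == "cold") w <- -w
  w[w < 0] <- 0
  w[!disc] <- 0
  if (sum(w) == 0) return(c(NA_real_, NA_real_))
  gx <- outer(cc$x, rep(1, length(cc$y)))
  gy <- outer(rep(1, length(cc$x)), cc$y)
  c(sum(gx * w), sum(gy * w)) / sum(w)
}

#' Timing-resolution sweep experiment
#'
#' Runs the study's TOF-quality experiment: one Monte Carlo acquisition with
#' perfect timing and energy resolution, re-blurred to each target timing
#' resolution (the resampling shortcut), windowed reconstruction per
#' resolution, and evaluation (CRC table, elongation ratios, kept-event
#' counts). Optionally writes images and tables into a run directory with a
#' machine-readable summary.
#'
#' @param phantom A `pet_phantom` (NEMA-IQ style, for CRC evaluation).
#' @param geom A [panel_geometry()].
#' @param roi An [roi_window()] for the windowed reconstruction.
#' @param fwhms Numeric vector of timing FWHMs to study, ps (default
#'   `c(100, 300, 1000)`).
#' @param n_decays Decays in the base acquisition.
#' @param n_iterations,n_subsets OSEM configuration.
#' @param seed RNG seed for the base acquisition and the re-blur draws.
#' @param elongation_lesion Lesion name whose elongation is tracked (default
#'   the 22 mm hot lesion).
#' @param out_dir Optional output directory for images and the summary JSON.
#' @param cache Optional prebuilt system cache (reused for every resolution).
#' @return List of class `tr_sweep`: `summary` (data frame per FWHM: kept
#'   events, CRCs of the tracked lesion, elongation ratio), `crc` (full CRC
#'   table), `recons` (named list of `pet_recon`).
#' @export
tr_sweep <- function(phantom, geom = panel_geometry(), roi, fwhms = c(100, 300, 1000),
                     n_decays = 5e5, n_iterations = 10, n_subsets = 16,
                     seed = 1, elongation_lesion = "hot_22mm", out_dir = NULL,
                     cache = NULL) {
  stopifnot(inherits(roi, "roi_window"))
  base <- simulate_listmode(phantom$image, geom,
                            acquisition_config(n_decays, timing_fwhm = 0,
                                               energy_fwhm_fraction = 0,
                                               seed = seed))
  if (is.null(cache)) cache <- build_system_cache(geom, phantom$image)
  les <- phantom$lesions
  eli <- match(elongation_lesion, les$name)
  if (is.na(eli)) stop("unknown elongation_lesion")
  bg <- background_mask(phantom)

  rows <- list()
  crcs <- list()
  recons <- list()
  for (i in seq_along(fwhms)) {
    f <- fwhms[i]
    blurred <- reblur_listmode(base, timing_fwhm = f, seed = seed + i)
    rec <- reconstruct_windowed(blurred, roi, geom = geom,
                                n_iterations = n_iterations,
                                n_subsets = n_subsets, cache = cache)
    tab <- crc_table(rec$image, phantom, bg, iteration = n_iterations,
                     timing_fwhm = f)
    # analysis window: generous around the lesion (taller in y, where the
    # limited-angle stretch develops) but clear of the bright ROI-edge
    # artifact band by a 6 mm margin
    hw <- c(min(1.8 * les$diameter[eli], les$x[eli] - roi$x_min - 6,
                roi$x_max - les$x[eli] - 6),
            min(3 * les$diameter[eli], les$y[eli] - roi$y_min - 6,
                roi$y_max - les$y[eli] - 6))
    el <- elongation_ratio(rec$image, c(les$x[eli], les$y[eli]),
                           halfwidth = hw)
    rows[[i]] <- data.frame(timing_fwhm = f, n_base = n_events(base),
                            n_kept = rec$counts$used,
                            crc_tracked = tab$crc[tab$lesion == elongation_lesion],
                            elongation = as.numeric(el$ratio))
    crcs[[i]] <- tab
    recons[[as.character(f)]] <- rec
  }
  out <- structure(list(summary = do.call(rbind, rows),
                        crc = do.call(rbind, crcs), recons = recons,
                        elongation_lesion = elongation_lesion, seed = seed),
                   class = "tr_sweep")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in names(recons))
      write_image(file.path(out_dir, sprintf("recon_%sps.img", f)),
                  recons[[f]]$image)
    write.csv(out$crc, file.path(out_dir, "crc.csv"), row.names = FALSE)
    jsonlite::write_json(list(summary = out$summary, seed = seed,
                              elongation_lesion = elongation_lesion),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.tr_sweep <- function(x, ...) {
  cat("Timing-resolution sweep\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
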