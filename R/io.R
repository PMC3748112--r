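#' Write list-mode data
#'
#' Two dialects selected by file extension: `.csv` (human-readable; header
#' `seq,crystal_a,crystal_b,delta_t_ps,energy_a_kev,energy_b_kev,true_x_mm,
#' true_y_mm`) and a flat little-endian binary (any other extension;
#' 32-byte records: uint32 seq, uint16 crystal_a, uint16 crystal_b, then six
#' float32: delta_t, energy_a, energy_b, true_x, true_y and a reserved zero).
#' Acquisition metadata goes to a JSON sidecar `<path>.json`.
#'
#' @param path Output file path.
#' @param data A `listmode`.
#' @return `path`, invisibly.
#' @export
write_listmode <- function(path, data) {
  stopifnot(inherits(data, "listmode"))
  ev <- data$events
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    out <- data.frame(seq = ev$seq, crystal_a = ev$crystal_a,
                      crystal_b = ev$crystal_b,
                      delta_t_ps = signif(ev$delta_t, 9),
                      energy_a_kev = signif(ev$energy_a, 9),
                      energy_b_kev = signif(ev$energy_b, 9),
                      true_x_mm = signif(ev$true_x, 9),
                      true_y_mm = signif(ev$true_y, 9))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    n <- nrow(ev)
    if (n > 0) {
      # assemble the 32-byte records column-wise in raw form, then interleave
      seq_raw <- writeBin(as.integer(ev$seq), raw(), size = 4,
                          endian = "little")
      ab_raw <- writeBin(as.integer(rbind(ev$crystal_a, ev$crystal_b)), raw(),
                         size = 2, endian = "little")
      fl_raw <- writeBin(as.numeric(rbind(ev$delta_t, ev$energy_a,
                                          ev$energy_b, ev$true_x, ev$true_y,
                                          rep(0, n))), raw(), size = 4,
                         endian = "little")
      rec <- rbind(matrix(seq_raw, 4, n), matrix(ab_raw, 4, n),
                   matrix(fl_raw, 24, n))
      writeBin(as.vector(rec), con)
    }
  }
  jsonlite::write_json(data$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read list-mode data
#'
#' @param path File written by [write_listmode()]; dialect by extension.
#' @return A `listmode`.
#' @export
read_listmode <- function(path) {
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    raw <- read.csv(path)
    need <- c("seq", "crystal_a", "crystal_b", "delta_t_ps", "energy_a_kev",
              "energy_b_kev", "true_x_mm", "true_y_mm")
    if (!all(need %in% names(raw))) stop("malformed list-mode CSV header")
    for (col in if (nrow(raw) > 0) need else character()) {
      if (!is.numeric(raw[[col]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))[1]
        stop(sprintf("non-numeric value in column '%s' at data line %d", col,
                     bad))
      }
    }
    ev <- data.frame(seq = as.integer(raw$seq),
                     crystal_a = as.integer(raw$crystal_a),
                     crystal_b = as.integer(raw$crystal_b),
                     delta_t = raw$delta_t_ps, energy_a = raw$energy_a_kev,
                     energy_b = raw$energy_b_kev, true_x = raw$true_x_mm,
                     true_y = raw$true_y_mm)
  } else {
    sz <- file.info(path)$size
    if (is.na(sz)) stop("cannot read ", path)
    if (sz %% 32 != 0) stop("corrupt binary list-mode file (size not a multiple of 32)")
    n <- sz %/% 32
    con <- file(path, "rb")
    on.exit(close(con))
    rec <- matrix(readBin(con, "raw", 32 * n), 32, n)
    seqv <- readBin(as.vector(rec[1:4, , drop = FALSE]), "integer", n,
                    size = 4, endian = "little")
    ab <- readBin(as.vector(rec[5:8, , drop = FALSE]), "integer", 2 * n,
                  size = 2, signed = FALSE, endian = "little")
    fl <- matrix(readBin(as.vector(rec[9:32, , drop = FALSE]), "numeric",
                         6 * n, size = 4, endian = "little"), 6, n)
    ev <- data.frame(seq = seqv,
                     crystal_a = ab[seq(1, length(ab), by = 2)],
                     crystal_b = ab[seq(2, length(ab), by = 2)],
                     delta_t = fl[1, ], energy_a = fl[2, ],
                     energy_b = fl[3, ], true_x = fl[4, ], true_y = fl[5, ])
  }
  new_listmode(ev, meta)
}

#' Write an image as flat float32 binary with JSON sidecar
#'
#' Row-major little-endian float32 pixel block (x fastest, lowest y row
#' first) plus a `<path>.json` sidecar recording shape, pixel size, origin
#' and units. Optionally an 8-bit min-max scaled PNG preview (marked
#' non-quantitative in the sidecar) if the `png` package is available.
#'
#' @param path Output path for the pixel block.
#' @param image A [pet_image()].
#' @param png_preview If TRUE, also write `<path>.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, image, png_preview = FALSE) {
  stopifnot(inherits(image, "pet_image"))
  g <- as_grid(image)
  con <- file(path, "wb")
  writeBin(as.numeric(image$values), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(
    list(shape = c(g$nx, g$ny), pixel_size_mm = g$px,
         origin_mm = c(g$x0, g$y0), units = image$units,
         slice_thickness_mm = image$slice_thickness,
         order = "x-fastest, float32 little-endian",
         png_preview = if (png_preview) "8-bit min-max scaled, non-quantitative" else NULL),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (png_preview) {
    if (!requireNamespace("png", quietly = TRUE))
      warning("png package not available; preview skipped")
    else {
      v <- image$values
      rng <- range(v)
      z <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
      # PNG rows run top to bottom: flip y and transpose to [row, col]
      png::writePNG(t(z[, rev(seq_len(ncol(z))), drop = FALSE]),
                    paste0(path, ".png"))
    }
  }
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path Pixel block path (sidecar `<path>.json` must exist).
#' @return A [pet_image()].
#' @export
read_image <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing image sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n + 1, size = 4, endian = "little")
  if (length(v) != n)
    stop("image payload does not match sidecar shape")
  pet_image(matrix(v, meta$shape[1], meta$shape[2]), meta$pixel_size_mm,
            meta$origin_mm, units = meta$units %||% "",
            slice_thickness = meta$slice_thickness_mm %||% 2)
}

#' Run a full pipeline from a configuration
#'
#' Executes phantom construction, acquisition, (optional) ROI discrimination,
#' reconstruction and evaluation from a validated configuration, writing every
#' stage's outputs and a manifest that allows exact re-execution into a run
#' directory.
#'
#' The configuration is a nested list (or a YAML file path) with blocks:
#' \describe{
#'   \item{geometry}{`panel_length_mm`, `panel_separation_mm`,
#'     `crystal_pitch_mm`}
#'   \item{phantom}{`type` ("nema_iq" or "abdomen"), plus arguments of the
#'     phantom constructor (without units suffix)}
#'   \item{acquisition}{`n_decays`, `timing_fwhm_ps`,
#'     `energy_fwhm_fraction`, `seed`}
#'   \item{recon}{`roi` (x_min, x_max, y_min, y_max; omit for conventional),
#'     `n_iterations`, `n_subsets`}
#'   \item{output}{`dir`}
#' }
#' Unknown keys are rejected before any computation starts.
#'
#' @param config Nested list or path to a YAML file.
#' @return The run directory path, invisibly; the directory contains the
#'   phantom, list-mode data, reconstruction, CRC table (NEMA phantom only)
#'   and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("geometry", "phantom", "acquisition", "recon", "output")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0)
    stop("unknown configuration block(s): ", paste(extra, collapse = ", "))
  gb <- config$geometry %||% list()
  extra <- setdiff(names(gb), c("panel_length_mm", "panel_separation_mm",
                                "crystal_pitch_mm"))
  if (length(extra) > 0)
    stop("unknown geometry key(s): ", paste(extra, collapse = ", "))
  geom <- panel_geometry(gb$panel_length_mm %||% 280,
                         gb$panel_separation_mm %||% 300,
                         gb$crystal_pitch_mm %||% 2)
  pb <- config$phantom %||% list(type = "nema_iq")
  type <- pb$type %||% "nema_iq"
  pargs <- pb[setdiff(names(pb), "type")]
  phan <- switch(type,
                 nema_iq = do.call(nema_iq_phantom, c(list(geom = geom), pargs)),
                 abdomen = do.call(abdomen_phantom, c(list(geom = geom), pargs)),
                 stop("unknown phantom type: ", type))
  ab <- config$acquisition %||% list()
  cfg <- acquisition_config(ab$n_decays %||% 1e5,
                            timing_fwhm = ab$timing_fwhm_ps %||% 300,
                            energy_fwhm_fraction = ab$energy_fwhm_fraction %||% 0.13,
                            seed = ab$seed %||% 1)
  rb <- config$recon %||% list()
  out_dir <- (config$output %||% list())$dir %||% tempfile("panelpet_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "phantom"
  manifest <- list(config = config, stages = list())
  tryCatch({
    write_image(file.path(out_dir, "phantom.img"), phan$image)
    manifest$stages$phantom <- list(file = "phantom.img")

    stage <- "simulate"
    lm <- simulate_listmode(phan$image, geom, cfg)
    write_listmode(file.path(out_dir, "listmode.lm"), lm)
    manifest$stages$simulate <- list(file = "listmode.lm",
                                     n_events = n_events(lm))

    stage <- "reconstruct"
    roi <- if (!is.null(rb$roi))
      roi_window(rb$roi$x_min, rb$roi$x_max, rb$roi$y_min, rb$roi$y_max,
                 geom = geom)
    rec <- reconstruct(lm, geom = geom, roi = roi,
                       n_iterations = rb$n_iterations %||% 10,
                       n_subsets = rb$n_subsets %||% 16)
    write_image(file.path(out_dir, "recon.img"), rec$image)
    write_image(file.path(out_dir, "recon_roi.img"), rec$roi_image)
    manifest$stages$reconstruct <- list(file = "recon.img",
                                        method = rec$method,
                                        events_used = rec$counts$used)

    stage <- "evaluate"
    if (type == "nema_iq") {
      tab <- crc_table(rec$image, phan, iteration = rb$n_iterations %||% 10,
                       timing_fwhm = cfg$timing_fwhm)
      write.csv(tab, file.path(out_dir, "crc.csv"), row.names = FALSE)
      manifest$stages$evaluate <- list(file = "crc.csv")
    }
  }, error = function(e) {
    manifest$failed_stage <<- stage
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
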