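#' 2D PET image
#'
#' A 2D grid of non-negative reals with square pixels. The value matrix is
#' indexed `values[ix, iy]` where ix increases with x and iy with y (so
#' `graphics::image()` displays it in scanner orientation). `origin` is the
#' lower-left corner of pixel (1, 1); pixel (ix, iy) has centre
#' `origin + (c(ix, iy) - 0.5) * pixel_size`.
#'
#' @param values Numeric matrix `[nx, ny]` of non-negative values.
#' @param pixel_size Pixel side in mm.
#' @param origin Length-2 numeric, lower-left corner of the grid in mm.
#' @param units Character label for the values (bookkeeping only).
#' @param slice_thickness Slice thickness in mm (bookkeeping for
#'   activity-to-decay conversion; both phantoms in the study are 2 mm thick).
#' @return Object of class `pet_image`.
#' @export
pet_image <- function(values, pixel_size, origin, units = "",
                      slice_thickness = 2) {
  values <- as.matrix(values)
  if (length(values) == 0) stop("empty image grid")
  if (any(!is.finite(values)) || any(values < 0))
    stop("image values must be finite and non-negative")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(values = values, pixel_size = pixel_size,
                 origin = as.numeric(origin), units = units,
                 slice_thickness = slice_thickness),
            class = "pet_image")
}

# normalized grid spec (nx, ny, px, x0, y0) from a pet_image or bare list
as_grid <- function(x) {
  if (inherits(x, "pet_image"))
    return(list(nx = nrow(x$values), ny = ncol(x$values), px = x$pixel_size,
                x0 = x$origin[1], y0 = x$origin[2]))
  if (is.list(x) && all(c("nx", "ny", "px", "x0", "y0") %in% names(x)))
    return(x)
  stop("cannot interpret grid specification")
}

#' Reconstruction/phantom grid covering the field of view
#'
#' @param geom A [panel_geometry()].
#' @param pixel_size Pixel side in mm; default 1 (half the 2 mm crystal
#'   pitch).
#' @return A zero-valued [pet_image()] spanning the FOV.
#' @export
fov_grid <- function(geom, pixel_size = 1) {
  nx <- round(geom$panel_length / pixel_size)
  ny <- round(geom$panel_separation / pixel_size)
  if (abs(nx * pixel_size - geom$panel_length) > 1e-9 ||
      abs(ny * pixel_size - geom$panel_separation) > 1e-9)
    stop("pixel_size must tile the field of view exactly")
  pet_image(matrix(0, nx, ny), pixel_size,
            c(-geom$panel_length / 2, -geom$panel_separation / 2))
}

#' Pixel centre coordinates of an image grid
#'
#' @param image A [pet_image()] (or grid spec).
#' @return List with vectors `x` (length nx) and `y` (length ny) in mm.
#' @export
pixel_centers <- function(image) {
  g <- as_grid(image)
  list(x = g$x0 + (seq_len(g$nx) - 0.5) * g$px,
       y = g$y0 + (seq_len(g$ny) - 0.5) * g$px)
}

#' @export
print.pet_image <- function(x, ...) {
  g <- as_grid(x)
  cat(sprintf("pet_image: %d x %d pixels, %g mm/pixel, origin (%g, %g) mm\n",
              g$nx, g$ny, g$px, g$x0, g$y0))
  cat(sprintf("  values in [%g, %g]%s\n", min(x$values), max(x$values),
              if (nzchar(x$units)) paste0(" ", x$units) else ""))
  invisible(x)
}

#' @export
plot.pet_image <- function(x, ..., main = NULL, col = gray.colors(256, 0, 1)) {
  cc <- pixel_centers(x)
  image(cc$x, cc$y, x$values, asp = 1, col = col, xlab = "x (mm)",
        ylab = "y (mm)", main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Crop an image to an ROI window
#'
#' Returns the sub-image of pixels whose centres fall inside the window.
#'
#' @param image A [pet_image()].
#' @param roi An [roi_window()].
#' @return A [pet_image()] covering the ROI.
#' @export
crop_image <- function(image, roi) {
  cc <- pixel_centers(image)
  ix <- which(cc$x >= roi$x_min & cc$x < roi$x_max)
  iy <- which(cc$y >= roi$y_min & cc$y < roi$y_max)
  if (length(ix) == 0 || length(iy) == 0) stop("ROI contains no pixel centres")
  pet_image(image$values[ix, iy, drop = FALSE], image$pixel_size,
            c(image$origin[1] + (min(ix) - 1) * image$pixel_size,
              image$origin[2] + (min(iy) - 1) * image$pixel_size),
            units = image$units, slice_thickness = image$slice_thickness)
}
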