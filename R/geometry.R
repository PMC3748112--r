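#' Dual-panel scanner geometry
#'
#' Two identical, parallel, horizontal panel detectors face each other across
#' the field of view, centred on and symmetric about the coordinate origin.
#' The top panel face lies at y = +`panel_separation`/2, the bottom at
#' -`panel_separation`/2. Crystals are indexed 0-based from the most negative
#' x; crystal k's front-face centre is at
#' x = -`panel_length`/2 + (k + 0.5) `crystal_pitch`. Detection happens at the
#' crystal front face (no depth of interaction).
#'
#' @param panel_length Panel length in mm (default 280, i.e. 28 cm).
#' @param panel_separation Face-to-face distance between panels in mm
#'   (default 300, i.e. 30 cm).
#' @param crystal_pitch Crystal pitch in mm (default 2). Must divide
#'   `panel_length` exactly.
#' @param crystal_depth Crystal depth in mm, informational only.
#' @return An object of class `panel_geometry` with fields `panel_length`,
#'   `panel_separation`, `crystal_pitch`, `n_crystals_per_panel`,
#'   `crystal_depth`.
#' @examples
#' geom <- panel_geometry()
#' geom$n_crystals_per_panel  # 140
#' @export
panel_geometry <- function(panel_length = 280, panel_separation = 300,
                           crystal_pitch = 2, crystal_depth = 10) {
  if (!is.numeric(panel_length) || panel_length <= 0 ||
      !is.numeric(panel_separation) || panel_separation <= 0 ||
      !is.numeric(crystal_pitch) || crystal_pitch <= 0)
    stop("panel_length, panel_separation and crystal_pitch must be positive")
  n <- panel_length / crystal_pitch
  if (abs(n - round(n)) > 1e-9)
    stop("panel_length must be an integer multiple of crystal_pitch")
  structure(list(panel_length = panel_length,
                 panel_separation = panel_separation,
                 crystal_pitch = crystal_pitch,
                 n_crystals_per_panel = as.integer(round(n)),
                 crystal_depth = crystal_depth),
            class = "panel_geometry")
}

#' @export
print.panel_geometry <- function(x, ...) {
  cat("Dual-panel PET geometry\n")
  cat(sprintf("  panel length:     %g mm (%d crystals, %g mm pitch)\n",
              x$panel_length, x$n_crystals_per_panel, x$crystal_pitch))
  cat(sprintf("  panel separation: %g mm (faces at y = %+g, %+g)\n",
              x$panel_separation, x$panel_separation / 2,
              -x$panel_separation / 2))
  cat(sprintf("  LORs:             %d\n",
              x$n_crystals_per_panel^2))
  invisible(x)
}

#' Crystal front-face centre x coordinates
#'
#' @param geom A [panel_geometry()].
#' @return Numeric vector of length `n_crystals_per_panel`, the x positions of
#'   crystal front-face centres (same for both panels).
#' @export
crystal_centers <- function(geom) {
  stopifnot(inherits(geom, "panel_geometry"))
  -geom$panel_length / 2 +
    (seq_len(geom$n_crystals_per_panel) - 0.5) * geom$crystal_pitch
}

#' Enumerate all lines of response
#'
#' Every (top, bottom) crystal pair is a valid LOR. Pairs are listed in
#' deterministic lexicographic order, `crystal_a` (top panel) major.
#'
#' @param geom A [panel_geometry()].
#' @return A data frame with columns `crystal_a`, `crystal_b` (0-based),
#'   `ax`, `ay`, `bx`, `by` (endpoint coordinates, mm).
#' @export
enumerate_lors <- function(geom) {
  cc <- crystal_centers(geom)
  n <- geom$n_crystals_per_panel
  H <- geom$panel_separation / 2
  a <- rep(seq_len(n) - 1L, each = n)
  b <- rep(seq_len(n) - 1L, times = n)
  data.frame(crystal_a = a, crystal_b = b,
             ax = cc[a + 1L], ay = H, bx = cc[b + 1L], by = -H)
}

#' Endpoints of one LOR
#'
#' @param geom A [panel_geometry()].
#' @param crystal_a,crystal_b 0-based crystal indices on the top and bottom
#'   panel.
#' @return List with `a` and `b`, each a length-2 numeric (x, y) in mm.
#' @export
lor_endpoints <- function(geom, crystal_a, crystal_b) {
  n <- geom$n_crystals_per_panel
  if (any(crystal_a < 0 | crystal_a >= n | crystal_b < 0 | crystal_b >= n))
    stop("crystal index out of range")
  cc <- crystal_centers(geom)
  H <- geom$panel_separation / 2
  list(a = cbind(cc[crystal_a + 1L], H), b = cbind(cc[crystal_b + 1L], -H))
}

#' TOF position along a LOR
#'
#' Maps a measured arrival-time difference to the implied annihilation point:
#' the LOR midpoint displaced by c*delta_t/2 along the unit vector from the
#' top-panel endpoint toward the bottom-panel endpoint. The sign convention is
#' delta_t = t_top - t_bottom, so a negative delta_t (earlier arrival at the
#' top crystal) displaces the point toward the top panel. The returned point
#' may lie outside the segment; callers decide what to do with it.
#'
#' @param geom A [panel_geometry()].
#' @param crystal_a,crystal_b 0-based crystal indices (vectors allowed).
#' @param delta_t Time difference(s) in ps.
#' @return An n x 2 matrix of (x, y) points in mm.
#' @export
tof_position <- function(geom, crystal_a, crystal_b, delta_t) {
  ep <- lor_endpoints(geom, crystal_a, crystal_b)
  dx <- ep$b[, 1] - ep$a[, 1]
  dy <- ep$b[, 2] - ep$a[, 2]
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0)) stop("degenerate LOR with coincident endpoints")
  d <- .C_MM_PER_PS * delta_t / 2
  cbind(x = (ep$a[, 1] + ep$b[, 1]) / 2 + d * dx / len,
        y = (ep$a[, 2] + ep$b[, 2]) / 2 + d * dy / len)
}

#' Axis-aligned rectangular region of interest
#'
#' @param x_min,x_max,y_min,y_max Edges in mm, scanner coordinates. Min edges
#'   are closed, max edges open (see [point_in_roi()]).
#' @param geom Optional [panel_geometry()]; if supplied, the rectangle is
#'   checked to lie inside the field of view (the region between the panels
#'   and within the panel extent).
#' @return An object of class `roi_window`.
#' @export
roi_window <- function(x_min, x_max, y_min, y_max, geom = NULL) {
  if (!(x_min < x_max && y_min < y_max))
    stop("ROI window requires x_min < x_max and y_min < y_max")
  if (!is.null(geom)) {
    fov <- fov_window(geom)
    if (x_min < fov$x_min - 1e-9 || x_max > fov$x_max + 1e-9 ||
        y_min < fov$y_min - 1e-9 || y_max > fov$y_max + 1e-9)
      stop("ROI window must lie inside the field of view")
  }
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "roi_window")
}

#' The full field of view as an ROI window
#'
#' The FOV is the rectangle between the two panel faces and within the panel
#' extent. The conventional (non-windowed) reconstruction mode is the windowed
#' algorithm run with this rectangle as its ROI.
#'
#' @param geom A [panel_geometry()].
#' @return An `roi_window` spanning the FOV.
#' @export
fov_window <- function(geom) {
  roi_window(-geom$panel_length / 2, geom$panel_length / 2,
             -geom$panel_separation / 2, geom$panel_separation / 2)
}

#' @export
print.roi_window <- function(x, ...) {
  cat(sprintf("ROI window: x in [%g, %g), y in [%g, %g) mm\n",
              x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

#' Point-in-ROI predicate
#'
#' Half-open convention: a point is inside iff
#' `x_min <= x < x_max` and `y_min <= y < y_max`.
#'
#' @param roi An [roi_window()].
#' @param point An n x 2 matrix (or length-2 vector) of (x, y) points in mm.
#' @return Logical vector.
#' @export
point_in_roi <- function(roi, point) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  point[, 1] >= roi$x_min & point[, 1] < roi$x_max &
    point[, 2] >= roi$y_min & point[, 2] < roi$y_max
}
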