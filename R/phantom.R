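#' Rasterize a disc onto an image grid
#'
#' A pixel belongs to the disc iff its centre lies strictly inside the circle.
#' No anti-aliasing: masks are exact pixel sets, which keeps region means and
#' contrast recovery coefficients well defined.
#'
#' @param grid A [pet_image()] or grid spec defining the raster.
#' @param center Length-2 numeric (x, y) disc centre in mm.
#' @param diameter Disc diameter in mm (> 0).
#' @return Logical matrix `[nx, ny]`.
#' @export
rasterize_disc <- function(grid, center, diameter) {
  if (diameter <= 0) stop("diameter must be positive")
  cc <- pixel_centers(grid)
  r2 <- (diameter / 2)^2
  outer((cc$x - center[1])^2, (cc$y - center[2])^2, `+`) < r2
}

# pixel-center-inside rasterization of an axis-aligned ellipse
rasterize_ellipse <- function(grid, center, semi_x, semi_y) {
  cc <- pixel_centers(grid)
  outer(((cc$x - center[1]) / semi_x)^2, ((cc$y - center[2]) / semi_y)^2,
        `+`) < 1
}

#' NEMA-IQ-style 2D activity phantom
#'
#' A single transverse slice of an image-quality phantom: an elliptical warm
#' body holding four hot discs (10, 13, 17 and 22 mm diameter) at
#' `hot_ratio` times the background activity and two cold discs (28 and
#' 37 mm) at zero, all centred on a ring about the phantom centre and equally
#' spaced in angle. The body ellipse axes and lesion ring radius are design
#' defaults chosen so that every lesion fits inside an imaging ROI within the
#' dual-panel FOV; both are configurable.
#'
#' @param geom A [panel_geometry()]; the raster covers its FOV.
#' @param pixel_size Pixel side in mm (default 1).
#' @param background_activity Background activity in kBq/cc (default 5.3).
#' @param hot_ratio Hot lesion to background uptake ratio (default 4).
#' @param body_semi_axes Length-2, body ellipse semi-axes (x, y) in mm.
#' @param lesion_ring_radius Radius of the circle of lesion centres in mm.
#' @param start_angle_deg Angle of the first (10 mm) lesion centre, degrees
#'   counter-clockwise from +x.
#' @return A list of class `pet_phantom` with elements `image`
#'   (a [pet_image()]), `regions` (named list of logical masks:
#'   `hot_10mm` ... `hot_22mm`, `cold_28mm`, `cold_37mm`, `body`,
#'   `background`), `lesions` (data frame of lesion name, kind, diameter and
#'   centre) and `hot_ratio`.
#' @export
nema_iq_phantom <- function(geom = panel_geometry(), pixel_size = 1,
                            background_activity = 5.3, hot_ratio = 4,
                            body_semi_axes = c(130, 100),
                            lesion_ring_radius = 57, start_angle_deg = 0) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (background_activity < 0 || hot_ratio < 0)
    stop("activity levels must be non-negative")
  grid <- fov_grid(geom, pixel_size)
  diam <- c(10, 13, 17, 22, 28, 37)
  kind <- c(rep("hot", 4), rep("cold", 2))
  ang <- (start_angle_deg + seq(0, 300, by = 60)) * pi / 180
  cx <- lesion_ring_radius * cos(ang)
  cy <- lesion_ring_radius * sin(ang)

  # every lesion must fit inside the body ellipse
  reach <- sqrt((cx / (body_semi_axes[1] - diam / 2))^2 +
                (cy / (body_semi_axes[2] - diam / 2))^2)
  if (any(body_semi_axes <= max(diam) / 2) || any(reach >= 1))
    stop("lesions exceed the body ellipse; adjust ring radius or body axes")

  body <- rasterize_ellipse(grid, c(0, 0), body_semi_axes[1], body_semi_axes[2])
  masks <- lapply(seq_along(diam), function(i)
    rasterize_disc(grid, c(cx[i], cy[i]), diam[i]))
  names(masks) <- paste0(kind, "_", diam, "mm")
  if (any(Reduce(`+`, masks) > 1)) stop("lesion masks overlap")

  values <- matrix(0, nrow(body), ncol(body))
  values[body] <- background_activity
  for (i in seq_along(masks)) {
    values[masks[[i]]] <- if (kind[i] == "hot")
      hot_ratio * background_activity else 0
  }
  background <- body & !Reduce(`|`, masks)

  img <- pet_image(values, pixel_size, grid$origin, units = "kBq/cc")
  structure(list(image = img,
                 regions = c(masks, list(body = body, background = background)),
                 lesions = data.frame(name = names(masks), kind = kind,
                                      diameter = diam, x = cx, y = cy),
                 hot_ratio = hot_ratio,
                 background_activity = background_activity),
            class = "pet_phantom")
}

#' Parametric 2D abdomen phantom
#'
#' A fully parametric stand-in for a single abdominal slice: an elliptical
#' body at muscle uptake, a crescent-shaped liver (a disc minus an offset
#' disc) at high uptake, a low-uptake spine disc, and one low-uptake lesion
#' disc inside the liver. The default lesion level is 1.5 times the muscle
#' background, below the liver level, so the lesion is a cold-ish defect
#' within the hot liver. Region intensities are arbitrary relative levels.
#'
#' @param geom A [panel_geometry()].
#' @param pixel_size Pixel side in mm.
#' @param levels Named list of activity levels: `muscle`, `liver`, `spine`,
#'   `lesion` (relative units; defaults 1, 4, 0.25, 1.5).
#' @param body_semi_axes Body ellipse semi-axes (x, y), mm.
#' @param liver_center,liver_radius Liver disc centre and radius, mm.
#' @param liver_cut_offset Offset of the subtracted disc producing the
#'   crescent, mm (added to `liver_center`).
#' @param spine_center,spine_radius Spine disc, mm.
#' @param lesion_center,lesion_diameter Lesion disc, mm. Must lie entirely
#'   inside the liver.
#' @return A `pet_phantom` list (image, regions `body`, `muscle`, `liver`,
#'   `spine`, `lesion`, plus `lesions` table).
#' @export
abdomen_phantom <- function(geom = panel_geometry(), pixel_size = 1,
                            levels = list(muscle = 1, liver = 4, spine = 0.25,
                                          lesion = 1.5),
                            body_semi_axes = c(120, 90),
                            liver_center = c(-40, 15), liver_radius = 55,
                            liver_cut_offset = c(55, -25),
                            spine_center = c(20, -55), spine_radius = 15,
                            lesion_center = c(-50, 25), lesion_diameter = 20) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  lv <- modifyList(list(muscle = 1, liver = 4, spine = 0.25, lesion = 1.5),
                   as.list(levels))
  if (any(unlist(lv) < 0)) stop("activity levels must be non-negative")
  grid <- fov_grid(geom, pixel_size)

  body <- rasterize_ellipse(grid, c(0, 0), body_semi_axes[1], body_semi_axes[2])
  liver_full <- rasterize_disc(grid, liver_center, 2 * liver_radius)
  liver_cut <- rasterize_disc(grid, liver_center + liver_cut_offset,
                              2 * liver_radius)
  liver <- liver_full & !liver_cut & body
  spine <- rasterize_disc(grid, spine_center, 2 * spine_radius) & body
  lesion <- rasterize_disc(grid, lesion_center, lesion_diameter)

  # geometric containment check (not just rasterized): lesion inside liver
  dc <- sqrt(sum((lesion_center - liver_center)^2))
  inside_disc <- dc + lesion_diameter / 2 < liver_radius
  cutc <- liver_center + liver_cut_offset
  dcut <- sqrt(sum((lesion_center - cutc)^2))
  clear_of_cut <- dcut - lesion_diameter / 2 > liver_radius
  if (!inside_disc || !clear_of_cut || !all(body[lesion]))
    stop("lesion must lie entirely inside the liver")
  if (any(spine & liver)) stop("spine and liver regions overlap")

  liver <- liver & !lesion
  muscle <- body & !liver & !spine & !lesion
  values <- matrix(0, nrow(body), ncol(body))
  values[muscle] <- lv$muscle
  values[liver] <- lv$liver
  values[spine] <- lv$spine
  values[lesion] <- lv$lesion

  img <- pet_image(values, pixel_size, grid$origin, units = "relative")
  structure(list(image = img,
                 regions = list(body = body, muscle = muscle, liver = liver,
                                spine = spine, lesion = lesion),
                 lesions = data.frame(name = "lesion", kind = "low_uptake",
                                      diameter = lesion_diameter,
                                      x = lesion_center[1],
                                      y = lesion_center[2]),
                 levels = lv),
            class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat("PET activity phantom\n")
  print(x$image)
  cat("  regions:", paste(names(x$regions), collapse = ", "), "\n")
  invisible(x)
}
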