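#' Specify histology preparation artefacts
#'
#' Parameters of the virtual sectioner emulating what fixation, dehydration
#' and paraffin embedding do to a vessel cross-section: an isotropic linear
#' shrink (crosslinking/dehydration contracts tissue, scaling areas by the
#' square of the factor) and a compression that flattens the circular lumen
#' into an ellipse while preserving the contour perimeter (embedding deforms
#' the wall but barely changes its length, which is why perimeter-based
#' lumen estimates are preferred over planimetry).
#'
#' @param shrink_factor Linear scale in (0, 1]; the default 0.77 makes
#'   section areas about 1.7 times smaller than in-vivo truth
#'   (1 / 0.77^2 ~ 1.69).
#' @param compression_ratio Ellipse major/minor axis ratio >= 1 applied at
#'   constant perimeter; 1 leaves sections circular.
#' @param plaque_fraction Fraction in [0, 1) of the shrunken media-circle
#'   area occupied by plaque in each section.
#' @param section_spacing Distance between sections along the vessel in mm
#'   (default 0.5, i.e. every 500 microns).
#' @param rng_seed Integer seed for the random in-plane orientation of the
#'   compression axis.
#' @return A `histology_artefacts` object.
#' @export
histology_artefacts <- function(shrink_factor = 0.77, compression_ratio = 1,
                                plaque_fraction = 0, section_spacing = 0.5,
                                rng_seed = 1L) {
  if (shrink_factor <= 0 || shrink_factor > 1)
    stop("`shrink_factor` must lie in (0, 1]", call. = FALSE)
  if (compression_ratio < 1)
    stop("`compression_ratio` must be >= 1", call. = FALSE)
  if (plaque_fraction < 0 || plaque_fraction >= 1)
    stop("`plaque_fraction` must lie in [0, 1)", call. = FALSE)
  if (section_spacing <= 0)
    stop("`section_spacing` must be positive", call. = FALSE)
  structure(list(shrink_factor = shrink_factor,
                 compression_ratio = compression_ratio,
                 plaque_fraction = plaque_fraction,
                 section_spacing = section_spacing,
                 rng_seed = as.integer(rng_seed)),
            class = "histology_artefacts")
}

# Perimeter of an ellipse with semi-axes a, b by numerical quadrature.
ellipse_perimeter <- function(a, b) {
  integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
            0, 2 * pi, rel.tol = 1e-10)$value
}

# Ellipse with axis ratio k and the same perimeter as a circle of radius r;
# returns semi-axes c(a, b) with a = k * b. Perimeter scales linearly with
# size, so matching is a single rescale of the unit-shape perimeter.
equal_perimeter_ellipse <- function(r, k) {
  p_circle <- 2 * pi * r
  s <- p_circle / ellipse_perimeter(k, 1)
  c(a = s * k, b = s)
}

ellipse_polygon <- function(a, b, angle = 0, n = 256L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(x = x * cos(angle) - y * sin(angle),
        y = x * sin(angle) + y * cos(angle))
}

#' Cut virtual histology sections from a synthetic vessel scene
#'
#' Sections are taken perpendicular to the true centerline at arc positions
#' 0, spacing, 2 x spacing, ... up to the vessel length. Each section's true
#' lumen circle (radius from the local true diameter) is scaled by the
#' shrink factor and then, when `compression_ratio > 1`, mapped to an
#' ellipse of equal perimeter with a seeded random in-plane orientation.
#' Two contours are emitted per section: the lumen-intima boundary and the
#' inner-media boundary (identical in these plaque-free wall geometries
#' before plaque is painted in); plaque area is a configured fraction of the
#' shrunken media-circle area, attached to the media contour.
#'
#' @param scene A [scene_spec()].
#' @param artefacts A [histology_artefacts()].
#' @return A tibble with one row per contour: `vessel_id`, `side`,
#'   `section_id`, `position_mm`, `role` (`"lumen"` or `"media"`),
#'   `contour` (list-column of n x 2 matrices, mm, in-section coordinates),
#'   `plaque_area_mm2` (media rows; 0 on lumen rows),
#'   `true_diameter_mm` and `true_area_mm2` for reference.
#' @export
virtual_histology <- function(scene, artefacts = histology_artefacts()) {
  stopifnot(inherits(scene, "scene_spec"), inherits(artefacts, "histology_artefacts"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(artefacts$rng_seed)

  purrr::map_dfr(scene$vessels, function(vs) {
    tr <- sample_vessel_truth(vs, scene$voxel_size)
    total <- tr$arc[length(tr$arc)]
    pos <- seq(0, total, by = artefacts$section_spacing)
    if (artefacts$section_spacing > total) {
      warn(paste0("section spacing exceeds vessel length for ", vs$vessel_id,
                  "; emitting a single section at position 0"))
      pos <- 0
    }
    purrr::map_dfr(seq_along(pos), function(si) {
      d_true <- stats::approx(tr$arc, tr$diameter, xout = pos[si])$y
      r_shr <- (d_true / 2) * artefacts$shrink_factor
      angle <- stats::runif(1, 0, pi)
      if (artefacts$compression_ratio > 1) {
        ab <- equal_perimeter_ellipse(r_shr, artefacts$compression_ratio)
        poly <- ellipse_polygon(ab[1], ab[2], angle)
      } else {
        poly <- ellipse_polygon(r_shr, r_shr)
      }
      plaque <- artefacts$plaque_fraction * pi * r_shr^2
      tibble::tibble(vessel_id = vs$vessel_id, side = vs$side,
                     section_id = si, position_mm = pos[si],
                     role = c("lumen", "media"),
                     contour = list(poly, poly),
                     plaque_area_mm2 = c(0, plaque),
                     true_diameter_mm = d_true,
                     true_area_mm2 = pi * d_true^2 / 4)
    })
  })
}
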