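#' Calibrate the lumen threshold from blood and muscle ROIs
#'
#' Computes the arithmetic mean intensity over a blood-pool region of
#' interest and a muscle region of interest, and sets the segmentation
#' threshold at their midpoint. The midpoint rule places the cut halfway
#' between the contrast-enhanced blood pool and soft tissue, which is where
#' the partial-volume ramp of a vessel wall crosses in a well-calibrated
#' scan.
#'
#' @param volume A [volume3d].
#' @param blood_roi,muscle_roi [roi_box()] regions in world mm; both must be
#'   non-empty and inside the volume.
#' @return An `intensity_calibration` list with `mean_blood`, `mean_muscle`,
#'   `threshold` (exactly their midpoint) and the voxel counts used.
#' @export
calibrate_intensity <- function(volume, blood_roi, muscle_roi) {
  stopifnot(inherits(volume, "volume3d"))
  bi <- roi_indices(volume, blood_roi)
  mi <- roi_indices(volume, muscle_roi)
  if (length(bi) == 0L) stop("blood ROI contains no voxels", call. = FALSE)
  if (length(mi) == 0L) stop("muscle ROI contains no voxels", call. = FALSE)
  if (length(intersect(bi, mi)) > 0L)
    warn("blood and muscle ROIs overlap; calibration may be biased")
  mb <- mean(volume$intensities[bi])
  mm <- mean(volume$intensities[mi])
  if (mb < mm)
    stop("blood ROI is darker than muscle ROI; check ROI placement", call. = FALSE)
  if (mb == mm)
    warn("degenerate contrast: blood and muscle ROI means are equal")
  structure(list(mean_blood = mb, mean_muscle = mm,
                 threshold = (mb + mm) / 2,
                 n_blood = length(bi), n_muscle = length(mi)),
            class = "intensity_calibration")
}

#' @export
print.intensity_calibration <- function(x, ...) {
  cat(sprintf("<intensity_calibration> blood %.3f (n=%d), muscle %.3f (n=%d), threshold %.3f\n",
              x$mean_blood, x$n_blood, x$mean_muscle, x$n_muscle, x$threshold))
  invisible(x)
}

# linear voxel indices inside an roi_box (world mm, inclusive)
roi_indices <- function(volume, roi) {
  stopifnot(inherits(roi, "roi_box"))
  d <- dim(volume$intensities)
  rng <- lapply(1:3, function(ax) {
    i0 <- ceiling((roi$lo[ax] - volume$origin[ax]) / volume$spacing[ax] - 1e-9) + 1
    i1 <- floor((roi$hi[ax] - volume$origin[ax]) / volume$spacing[ax] + 1e-9) + 1
    seq2 <- seq.int(max(i0, 1L), min(i1, d[ax]))
    if (i0 > d[ax] || i1 < 1L) integer(0) else seq2
  })
  if (any(lengths(rng) == 0L)) return(integer(0))
  idx <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  (idx$i) + d[1] * (idx$j - 1) + d[1] * d[2] * (idx$k - 1)
}

#' Segment the vessel lumen by midpoint thresholding
#'
#' Thresholds the volume at the calibrated midpoint of blood and muscle
#' intensity, then restricts the result to the 26-connected component
#' containing the seed point, so that only the seeded vessel is kept even
#' when other contrast-filled structures cross the threshold.
#'
#' @param volume A [volume3d].
#' @param calibration An `intensity_calibration` from
#'   [calibrate_intensity()], or a single numeric threshold.
#' @param seed_point World coordinates (mm) of a point inside the vessel;
#'   snapped to the nearest voxel. Its intensity must be at or above the
#'   threshold.
#' @param closing_radius Radius (voxels) of an optional morphological
#'   closing applied to the thresholded volume before component extraction;
#'   default 0 (off).
#' @return A `segmentation_mask`: logical array `mask` plus `spacing`,
#'   `origin` and a `provenance` record (threshold and seed used).
#' @export
segment_lumen <- function(volume, calibration, seed_point, closing_radius = 0L) {
  stopifnot(inherits(volume, "volume3d"))
  thr <- if (inherits(calibration, "intensity_calibration")) calibration$threshold
         else as.numeric(calibration)
  d <- dim(volume$intensities)
  si <- pmin(pmax(world_to_index(volume, seed_point), 1L), d)
  above <- volume$intensities >= thr
  if (closing_radius > 0L) above <- morph_close(above, closing_radius)
  if (!above[si[1], si[2], si[3]])
    stop(sprintf("seed point intensity %.3f is below the threshold %.3f",
                 volume$intensities[si[1], si[2], si[3]], thr), call. = FALSE)
  lin <- (si[1] - 1) + d[1] * (si[2] - 1) + d[1] * d[2] * (si[3] - 1)
  comp <- cpp_flood_fill(above, as.integer(d), as.numeric(lin))
  structure(list(mask = array(as.logical(comp), dim = d),
                 spacing = volume$spacing, origin = volume$origin,
                 provenance = list(threshold = thr, seed_point = as.numeric(seed_point),
                                   closing_radius = closing_radius)),
            class = "segmentation_mask")
}

# binary closing with a cubic structuring element via distance transforms
morph_close <- function(mask, radius) {
  d <- dim(mask)
  sp <- c(1, 1, 1)
  # dilate: background voxels within `radius` of foreground (grid borders are
  # treated as foreground by the transform; closing is an opt-in cosmetic step)
  dist_to_fg <- cpp_edt(array(!mask, dim = d), as.integer(d), sp)
  dil <- mask | (dist_to_fg > 0 & dist_to_fg <= radius + 1e-9)
  # erode the dilation: drop voxels within `radius` of its background
  dist_to_bg <- cpp_edt(array(dil, dim = d), as.integer(d), sp)
  array(dil & dist_to_bg > radius + 1e-9, dim = d)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %s voxels in component, threshold %.3f\n",
              format(sum(x$mask), big.mark = ","), x$provenance$threshold))
  invisible(x)
}

#' Physical volume of a segmentation mask
#' @param mask A `segmentation_mask`.
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  sum(mask$mask) * prod(mask$spacing)
}
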