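#' Specify a synthetic vessel
#'
#' Describes one curved, optionally stenosed vessel for the phantom
#' generator. The centerline is a Catmull-Rom spline through the control
#' points, resampled to uniform arc length; local lumen diameter is the base
#' diameter modulated by smooth (raised-cosine) stenoses. Severity below 1
#' means the lumen is narrowed but never fully occluded, mirroring partial
#' ligation.
#'
#' @param control_points Numeric matrix (>= 2 rows, 3 columns), centerline
#'   control points in mm. Consecutive duplicate points are rejected.
#' @param base_diameter Lumen diameter in mm away from stenoses; must be
#'   positive. The default is a typical murine left common carotid diameter.
#' @param stenoses Data frame (or tibble) with columns `position` (fraction
#'   of arc length, strictly inside (0,1)), `severity` (diameter reduction
#'   fraction in [0,1)) and `extent` (fraction of arc length covered,
#'   in (0,1]). `NULL` for a healthy vessel.
#' @param length Target arc length in mm. When given, the spline is scaled
#'   about its start point so the centerline arc length equals it; when
#'   `NULL` the control-point geometry sets the length.
#' @param vessel_id,side Labels carried through to profiles.
#' @return A `vessel_spec` object.
#' @export
vessel_spec <- function(control_points, base_diameter = 0.328, stenoses = NULL,
                        length = NULL, vessel_id = "V1", side = "LCCA") {
  control_points <- as.matrix(control_points)
  if (ncol(control_points) != 3L || nrow(control_points) < 2L)
    stop("`control_points` must be an n x 3 matrix with n >= 2", call. = FALSE)
  steps <- sqrt(rowSums((control_points[-1, , drop = FALSE] -
                         control_points[-nrow(control_points), , drop = FALSE])^2))
  if (any(steps <= 0))
    stop("control-point parameterization must be strictly increasing ",
         "(consecutive duplicate control points)", call. = FALSE)
  if (!is.finite(base_diameter) || base_diameter <= 0)
    stop("`base_diameter` must be positive", call. = FALSE)
  if (!is.null(stenoses)) {
    stenoses <- as.data.frame(stenoses)
    stopifnot(all(c("position", "severity", "extent") %in% names(stenoses)))
    if (any(stenoses$position <= 0 | stenoses$position >= 1))
      stop("stenosis `position` must lie strictly inside (0, 1)", call. = FALSE)
    if (any(stenoses$severity < 0 | stenoses$severity >= 1))
      stop("stenosis `severity` must lie in [0, 1): the lumen is never fully occluded",
           call. = FALSE)
    if (any(stenoses$extent <= 0 | stenoses$extent > 1))
      stop("stenosis `extent` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(control_points = control_points, base_diameter = base_diameter,
                 stenoses = stenoses, length = length,
                 vessel_id = vessel_id, side = side),
            class = "vessel_spec")
}

#' Specify a synthetic micro-CT scene
#'
#' Collects vessels and image-formation parameters for [build_phantom()].
#' Default intensities emulate in vivo contrast-enhanced neck CT: blood-pool
#' intensity 148.3 units with Gaussian noise of SD 2.0, at 18 micron
#' isotropic voxels. The muscle intensity is a free parameter of the scene
#' (only blood is calibrated by published values); the default 100 places
#' soft tissue well below the contrast-enhanced blood pool. The background
#' default 90 models unenhanced perivascular soft tissue just below muscle:
#' in a neck scan the vessel wall borders tissue, not air, and the midpoint
#' threshold then cuts the blood-to-surroundings partial-volume ramp close
#' to its half-occupancy point.
#'
#' @param vessels A `vessel_spec` or list of them.
#' @param intensity_blood,intensity_muscle,intensity_background Mean
#'   intensities (arbitrary units); must satisfy blood > muscle > background.
#' @param voxel_size mm per axis (scalar for isotropic, or length 3).
#' @param psf_sigma Gaussian point-spread sigma in mm (0 disables blur).
#' @param noise_sd Additive Gaussian noise SD in intensity units (>= 0).
#' @param rng_seed Integer seed for the noise; required for reproducibility.
#' @param dim Optional explicit grid size (voxels). When `NULL` the grid is
#'   auto-fitted around the vessels with a safety margin.
#' @param margin_mm Extra world-space margin around the vessel bounding box
#'   when auto-fitting.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(vessels, intensity_blood = 148.3, intensity_muscle = 100,
                       intensity_background = 90, voxel_size = 0.018,
                       psf_sigma = 0.018, noise_sd = 2.0, rng_seed = 1L,
                       dim = NULL, margin_mm = NULL) {
  if (inherits(vessels, "vessel_spec")) vessels <- list(vessels)
  stopifnot(length(vessels) >= 1L,
            all(vapply(vessels, inherits, logical(1), "vessel_spec")))
  if (!(intensity_blood > intensity_muscle && intensity_muscle > intensity_background))
    stop("intensities must satisfy blood > muscle > background", call. = FALSE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (psf_sigma < 0) stop("`psf_sigma` must be >= 0", call. = FALSE)
  structure(list(vessels = vessels, intensity_blood = intensity_blood,
                 intensity_muscle = intensity_muscle,
                 intensity_background = intensity_background,
                 voxel_size = as.numeric(voxel_size), psf_sigma = psf_sigma,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed),
                 dim = dim, margin_mm = margin_mm),
            class = "scene_spec")
}

# Uniform Catmull-Rom spline through control points, arc-length resampled to
# steps of `step` mm. Ends are extended by reflection so the curve passes
# through the first and last control point.
catmull_rom_centerline <- function(p, step, per_segment = 64L) {
  n <- nrow(p)
  if (n == 2L) {
    len <- sqrt(sum((p[2, ] - p[1, ])^2))
    ns <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = ns)
    return(cbind(p[1, 1] + t * (p[2, 1] - p[1, 1]),
                 p[1, 2] + t * (p[2, 2] - p[1, 2]),
                 p[1, 3] + t * (p[2, 3] - p[1, 3])))
  }
  ext <- rbind(2 * p[1, ] - p[2, ], p, 2 * p[n, ] - p[n - 1, ])
  dense <- vector("list", n - 1L)
  for (seg in seq_len(n - 1L)) {
    p0 <- ext[seg, ]; p1 <- ext[seg + 1, ]; p2 <- ext[seg + 2, ]; p3 <- ext[seg + 3, ]
    t <- seq(0, 1, length.out = per_segment + 1L)
    if (seg < n - 1L) t <- t[-length(t)]
    t2 <- t * t; t3 <- t2 * t
    m <- cbind(-0.5 * t3 + t2 - 0.5 * t,
               1.5 * t3 - 2.5 * t2 + 1,
               -1.5 * t3 + 2 * t2 + 0.5 * t,
               0.5 * t3 - 0.5 * t2)
    dense[[seg]] <- m %*% rbind(p0, p1, p2, p3)
  }
  dense <- do.call(rbind, dense)
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- arc[length(arc)]
  ns <- max(2L, ceiling(total / step) + 1L)
  s <- seq(0, total, length.out = ns)
  cbind(stats::approx(arc, dense[, 1], xout = s)$y,
        stats::approx(arc, dense[, 2], xout = s)$y,
        stats::approx(arc, dense[, 3], xout = s)$y)
}

# Diameter at normalized arc positions t in [0, 1]: raised-cosine stenoses.
vessel_diameter_at <- function(spec, t) {
  d <- rep(spec$base_diameter, length(t))
  if (!is.null(spec$stenoses)) {
    for (i in seq_len(nrow(spec$stenoses))) {
      p <- spec$stenoses$position[i]
      s <- spec$stenoses$severity[i]
      half <- spec$stenoses$extent[i] / 2
      w <- abs(t - p) <= half
      bump <- numeric(length(t))
      bump[w] <- 0.5 * (1 + cos(pi * (t[w] - p) / half))
      d <- d * (1 - s * bump)
    }
  }
  d
}

# Resolve a vessel to its ground-truth sampling: points (mm), arc (mm),
# diameter (mm). Arc step <= half the smallest voxel.
sample_vessel_truth <- function(spec, voxel_size) {
  step <- min(voxel_size) / 2
  pts <- catmull_rom_centerline(spec$control_points, step)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- arc[length(arc)]
  if (!is.null(spec$length) && spec$length > 0) {
    sc <- spec$length / total
    pts <- sweep(sweep(pts, 2, pts[1, ], "-") * sc, 2, pts[1, ], "+")
    arc <- arc * sc
    total <- spec$length
    if (sc > 1.5) { # keep arc steps at half-voxel after upscaling
      pts <- catmull_rom_centerline(pts, step)
      arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
      total <- arc[length(arc)]
    }
  }
  list(points = pts, arc = arc,
       diameter = vessel_diameter_at(spec, arc / total))
}

# Nine-segment truth profile by arc-length binning of the true diameters.
truth_segment_profile <- function(arc, diameter, n_segments = 9L) {
  t <- arc / arc[length(arc)]
  seg <- pmin(floor(t * n_segments) + 1L, n_segments)
  d <- vapply(seq_len(n_segments), function(i) mean(diameter[seg == i]), numeric(1))
  tibble::tibble(segment = seq_len(n_segments), diameter_mm = d,
                 area_mm2 = pi * d^2 / 4)
}

#' Build a synthetic contrast-enhanced micro-CT volume with known truth
#'
#' Renders each vessel as a partial-volume tube (3x3x3 supersampled
#' occupancy against the tube's signed distance), maps occupancy to
#' intensity between background and blood, convolves with an isotropic
#' Gaussian point-spread function, and adds seeded Gaussian noise. A cuboid
#' of muscle intensity is placed a fixed 10 voxels beside the first vessel
#' so that downstream intensity calibration has a soft-tissue region of
#' interest, and matching blood/muscle ROI boxes are returned.
#'
#' @param scene A [scene_spec()].
#' @return A `lumen_phantom` list with elements `volume` ([volume3d]),
#'   `truth` (tibble of centerline samples: `vessel_id`, `side`, `x_mm`,
#'   `y_mm`, `z_mm`, `arc_mm`, `diameter_mm`), `truth_profile` (tibble of
#'   nine-segment true diameters/areas per vessel), `blood_roi` and
#'   `muscle_roi` (axis-aligned boxes in mm), `seed_points` (tibble of
#'   per-vessel start/end points in mm) and the `scene` itself.
#' @export
build_phantom <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  sp <- scene$voxel_size
  truths <- lapply(scene$vessels, sample_vessel_truth, voxel_size = sp)

  # rendered tube gets a short stump beyond each centerline end (the artery
  # continues beyond both seed points in vivo); truth keeps the seeded span
  renders <- lapply(truths, function(tr) {
    pts <- tr$points; rad <- tr$diameter / 2
    n <- nrow(pts)
    step <- min(sp) / 2
    ext_end <- function(p_end, p_prev, r) {
      if (1.5 * r < step)
        return(list(pts = matrix(numeric(0), 0, 3), rad = numeric(0)))
      tg <- p_end - p_prev
      tg <- tg / sqrt(sum(tg^2))
      s <- seq(step, 1.5 * r, by = step)
      list(pts = sweep(outer(s, tg), 2, p_end, "+"), rad = rep(r, length(s)))
    }
    head_ext <- ext_end(pts[1, ], pts[2, ], rad[1])
    tail_ext <- ext_end(pts[n, ], pts[n - 1, ], rad[n])
    list(points = rbind(head_ext$pts[rev(seq_len(nrow(head_ext$pts))), ], pts,
                        tail_ext$pts),
         radius = c(rev(head_ext$rad), rad, tail_ext$rad))
  })

  max_r <- max(vapply(seq_along(truths), function(i) max(truths[[i]]$diameter) / 2,
                      numeric(1)))
  margin <- scene$margin_mm %||% (max_r + 3 * scene$psf_sigma + 6 * max(sp))
  all_pts <- do.call(rbind, lapply(renders, `[[`, "points"))
  lo <- apply(all_pts, 2, min) - margin
  hi <- apply(all_pts, 2, max) + margin
  # reserve room for the muscle calibration block beyond +x of the vessels
  block_vox <- 8L
  hi[1] <- hi[1] + (10L + block_vox + 2L) * sp[1]

  if (is.null(scene$dim)) {
    nd <- pmax(ceiling((hi - lo) / sp) + 1, 8)
    origin <- lo
  } else {
    nd <- as.integer(scene$dim)
    origin <- lo
    need <- ceiling((hi - lo) / sp) + 1
    if (any(nd < need))
      stop("vessel (plus margin) does not fit inside the requested grid: needs ",
           paste(need, collapse = " x "), " voxels, got ",
           paste(nd, collapse = " x "), call. = FALSE)
  }
  # >= 2 voxel margin check against the actual bounds
  ext_hi <- origin + (nd - 1) * sp
  tube_lo <- apply(all_pts, 2, min) - max_r
  tube_hi <- apply(all_pts, 2, max) + max_r
  if (any(tube_lo < origin + 2 * sp) || any(tube_hi > ext_hi - 2 * sp))
    stop("vessel lies outside the volume bounds (needs >= 2 voxels margin)",
         call. = FALSE)

  occ <- array(0, dim = nd)
  for (rd in renders) {
    win <- ceiling(2 * max(sp) / (min(sp) / 2)) + 2L
    occ_v <- cpp_fill_occupancy(as.integer(nd), sp, origin, rd$points,
                                rd$radius, as.integer(win))
    occ <- pmin(occ + occ_v, 1)
  }

  vol <- scene$intensity_background +
    (scene$intensity_blood - scene$intensity_background) * occ

  # muscle block: fixed geometry, 10 voxels beyond the vessel bounding box in +x
  bb_hi_i <- world_to_index(list(origin = origin, spacing = sp), tube_hi)
  mid <- colMeans(all_pts)
  mid_i <- world_to_index(list(origin = origin, spacing = sp), mid)
  mb_i0 <- min(bb_hi_i[1] + 10L, nd[1] - block_vox)
  mb_i1 <- mb_i0 + block_vox - 1L
  mb_j <- pmax(1L, pmin(nd[2], mid_i[2] + seq(0L, block_vox - 1L) - block_vox %/% 2L))
  mb_k <- pmax(1L, pmin(nd[3], mid_i[3] + seq(0L, block_vox - 1L) - block_vox %/% 2L))
  vol[mb_i0:mb_i1, mb_j, mb_k] <- scene$intensity_muscle
  muscle_roi <- roi_box(
    lo = origin + (c(mb_i0, min(mb_j), min(mb_k)) - 1) * sp,
    hi = origin + (c(mb_i1, max(mb_j), max(mb_k)) - 1) * sp)

  if (scene$psf_sigma > 0) {
    for (ax in 0:2) {
      sig <- scene$psf_sigma / sp[ax + 1]
      rad <- max(1L, ceiling(3 * sig))
      k <- dnorm(seq(-rad, rad), sd = sig)
      vol <- cpp_convolve_axis(vol, as.integer(nd), k / sum(k), ax)
    }
  }

  if (scene$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(scene$rng_seed)
    vol <- vol + array(rnorm(prod(nd), 0, scene$noise_sd), dim = nd)
  }

  # blood ROI: small box inside the first vessel at mid-arc
  tr1 <- truths[[1]]
  mid_s <- which.min(abs(tr1$arc - tr1$arc[length(tr1$arc)] / 2))
  half <- tr1$diameter[mid_s] / 2 * 0.35
  blood_roi <- roi_box(lo = tr1$points[mid_s, ] - half,
                       hi = tr1$points[mid_s, ] + half)

  truth <- dplyr::bind_rows(lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]; vs <- scene$vessels[[i]]
    tibble::tibble(vessel_id = vs$vessel_id, side = vs$side,
                   x_mm = tr$points[, 1], y_mm = tr$points[, 2],
                   z_mm = tr$points[, 3], arc_mm = tr$arc,
                   diameter_mm = tr$diameter)
  }))
  truth_profile <- dplyr::bind_rows(lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]; vs <- scene$vessels[[i]]
    dplyr::mutate(truth_segment_profile(tr$arc, tr$diameter),
                  vessel_id = vs$vessel_id, side = vs$side, .before = 1)
  }))
  seed_points <- dplyr::bind_rows(lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]; vs <- scene$vessels[[i]]
    n <- nrow(tr$points)
    tibble::tibble(vessel_id = vs$vessel_id,
                   end = c("start", "end"),
                   x_mm = tr$points[c(1, n), 1], y_mm = tr$points[c(1, n), 2],
                   z_mm = tr$points[c(1, n), 3])
  }))

  structure(list(volume = volume3d(vol, spacing = sp, origin = origin),
                 truth = truth, truth_profile = truth_profile,
                 blood_roi = blood_roi, muscle_roi = muscle_roi,
                 seed_points = seed_points, scene = scene),
            class = "lumen_phantom")
}

#' Axis-aligned world-space box (mm) used as a region of interest
#' @param lo,hi Numeric length-3 corners in mm, `lo <= hi` per axis.
#' @return A `roi_box` object.
#' @export
roi_box <- function(lo, hi) {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(lo <= hi))
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)), class = "roi_box")
}

#' @export
print.lumen_phantom <- function(x, ...) {
  cat(sprintf("<lumen_phantom> %d vessel(s)\n", length(x$scene$vessels)))
  print(x$volume)
  invisible(x)
}
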