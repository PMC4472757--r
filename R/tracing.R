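#' Euclidean distance map of a segmentation mask
#'
#' For every lumen voxel, the anisotropy-aware Euclidean distance (mm) to
#' the nearest background voxel center; zero outside the mask. Voxels
#' beyond the grid count as background, so a mask touching the volume
#' border is not treated as extending past it. This distance is the radius
#' of the largest sphere inscribed at each voxel, the quantity the elastic
#' sphere reads out.
#'
#' @param mask A `segmentation_mask` (or logical array, with `spacing`).
#' @param spacing Voxel spacing in mm, only needed when `mask` is a bare
#'   array.
#' @return Numeric 3D array of distances in mm.
#' @export
distance_map <- function(mask, spacing = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    arr <- mask$mask
    spacing <- mask$spacing
  } else {
    arr <- mask
    if (is.null(spacing)) stop("`spacing` required for a bare array", call. = FALSE)
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  }
  if (!any(arr)) stop("mask is empty", call. = FALSE)
  cpp_edt(array(as.logical(arr), dim = dim(arr)), as.integer(dim(arr)),
          as.numeric(spacing))
}

snap_seed <- function(arr, spacing, origin, point, snap_voxels = 5L) {
  d <- dim(arr)
  si <- round((as.numeric(point) - origin) / spacing) + 1
  if (all(si >= 1) && all(si <= d) && arr[si[1], si[2], si[3]])
    return(si)
  rng <- lapply(1:3, function(ax) {
    lo <- max(si[ax] - snap_voxels, 1L); hi <- min(si[ax] + snap_voxels, d[ax])
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0L))
    stop("seed point ", paste(signif(point, 4), collapse = ", "),
         " mm is not within ", snap_voxels, " voxels of the mask", call. = FALSE)
  g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  inside <- arr[g]
  if (!any(inside))
    stop("seed point ", paste(signif(point, 4), collapse = ", "),
         " mm is not within ", snap_voxels, " voxels of the mask", call. = FALSE)
  g <- g[inside, , drop = FALSE]
  w <- sweep(g, 2, si, "-")
  dist2 <- (w[, 1] * spacing[1])^2 + (w[, 2] * spacing[2])^2 + (w[, 3] * spacing[3])^2
  g[which.min(dist2), ]
}

#' Trace the lumen between two seed points (virtual elastic sphere)
#'
#' Finds, among all 26-connected voxel paths through the mask, the path
#' minimizing the radius-weighted length `sum(step / r)`, where `r` is the
#' local inscribed-sphere radius from the distance map. This is the track a
#' maximally inflated sphere follows as it slides from the start seed to
#' the end seed: narrow or off-center voxels are expensive, so the path
#' hugs the medial axis. Seeds given in mm are snapped to the nearest mask
#' voxel within a 5-voxel ball. The traced polyline is smoothed with a
#' 3-point moving average (endpoints fixed) before arc lengths are
#' accumulated.
#'
#' @param mask A `segmentation_mask`.
#' @param start,end World coordinates (mm) of the start and end seeds.
#' @param dmap Optional precomputed [distance_map()] (recomputed otherwise).
#' @return A `lumen_trace` tibble with columns `index`, `x_mm`, `y_mm`,
#'   `z_mm`, `radius_mm`, `arc_mm`; the optimal path cost is attached as
#'   attribute `cost`.
#' @export
trace_lumen <- function(mask, start, end, dmap = NULL) {
  stopifnot(inherits(mask, "segmentation_mask"))
  arr <- mask$mask
  d <- dim(arr)
  sp <- mask$spacing
  if (is.null(dmap)) dmap <- distance_map(mask)
  s0 <- snap_seed(arr, sp, mask$origin, start)
  s1 <- snap_seed(arr, sp, mask$origin, end)
  lin0 <- (s0[1] - 1) + d[1] * (s0[2] - 1) + d[1] * d[2] * (s0[3] - 1)
  lin1 <- (s1[1] - 1) + d[1] * (s1[2] - 1) + d[1] * d[2] * (s1[3] - 1)

  res <- cpp_trace_path(array(as.logical(arr), dim = d), as.integer(d),
                        as.numeric(sp), as.numeric(dmap),
                        as.numeric(lin0), as.numeric(lin1))
  if (!isTRUE(res$reached))
    stop("start and end seeds lie in different connected components of the mask",
         call. = FALSE)
  lin <- as.numeric(res$path)
  i <- lin %% d[1] + 1
  j <- (lin %/% d[1]) %% d[2] + 1
  k <- lin %/% (d[1] * d[2]) + 1

  pts <- cbind(mask$origin[1] + (i - 1) * sp[1],
               mask$origin[2] + (j - 1) * sp[2],
               mask$origin[3] + (k - 1) * sp[3])
  n <- nrow(pts)
  if (n >= 3L) {
    sm <- (pts[1:(n - 2), ] + pts[2:(n - 1), ] + pts[3:n, ]) / 3
    pts[2:(n - 1), ] <- sm
  }
  arc <- if (n == 1L) 0 else c(0, cumsum(sqrt(rowSums(diff(pts)^2))))

  # sub-voxel sphere inflation: the sphere center slides in the plane
  # perpendicular to the local path tangent (it must stay at this arc
  # position) and inflates until it touches a background voxel center. The
  # voxel path itself can ride up to half a voxel off the medial axis, which
  # a grid-sampled distance map cannot resolve.
  tangents <- if (n == 1L) matrix(c(1, 0, 0), 1) else {
    tg <- rbind(pts[2, ] - pts[1, ],
                if (n > 2L) pts[3:n, ] - pts[1:(n - 2), ],
                pts[n, ] - pts[n - 1, ])
    tg[seq_len(n), , drop = FALSE]
  }
  r_hint <- dmap[cbind(i, j, k)]
  radius <- cpp_sphere_radius(array(as.logical(arr), dim = d), as.integer(d),
                              as.numeric(sp), as.numeric(mask$origin),
                              pts, tangents, r_hint,
                              max_shift = max(sp), step = min(sp) / 4)
  if (any(r_hint <= min(sp) + 1e-12))
    warn("inscribed-sphere radius falls below one voxel along the path (near-occlusion)")

  out <- tibble::tibble(index = seq_len(n), x_mm = pts[, 1], y_mm = pts[, 2],
                        z_mm = pts[, 3], radius_mm = radius, arc_mm = arc)
  attr(out, "cost") <- res$cost
  class(out) <- c("lumen_trace", class(out))
  out
}

#' Per-point lumen diameter along a trace
#'
#' The elastic-sphere readout: local diameter is twice the inscribed-sphere
#' radius, paired with cumulative arc length along the traced centerline.
#'
#' @param path A `lumen_trace` from [trace_lumen()], or any data frame with
#'   `radius_mm` and `arc_mm` columns.
#' @return A tibble with `arc_mm` and `diameter_mm`.
#' @export
diameter_profile <- function(path) {
  stopifnot(all(c("radius_mm", "arc_mm") %in% names(path)))
  tibble::tibble(arc_mm = path$arc_mm, diameter_mm = 2 * path$radius_mm)
}
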