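#' Perimeter and planimetric area of a section contour
#'
#' Classical planimetry of a digitized closed contour: the perimeter is the
#' sum of edge lengths and the area is the absolute value of the
#' surveyor's (shoelace) formula. Both are invariant to vertex orientation.
#' Self-intersecting polygons are rejected; zero-area contours raise a
#' warning.
#'
#' @param contour An n x 2 matrix of vertices (n >= 3), closed implicitly
#'   (last vertex connects back to the first). Units are whatever the
#'   contour is in; see [read_sections()] for unit handling on load.
#' @return A tibble with `perimeter` and `planimetric_area`.
#' @export
polygon_metrics <- function(contour) {
  contour <- as.matrix(contour)
  if (ncol(contour) != 2L || nrow(contour) < 3L)
    stop("contour must be an n x 2 matrix with n >= 3 vertices", call. = FALSE)
  if (any(!is.finite(contour))) stop("contour has non-finite vertices", call. = FALSE)
  if (polygon_self_intersects(contour))
    stop("contour is self-intersecting; planimetry requires a simple polygon",
         call. = FALSE)
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  per <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  area <- abs(sum(x * yn - xn * y)) / 2
  if (area == 0) warn("degenerate contour with zero area")
  tibble::tibble(perimeter = per, planimetric_area = area)
}

# O(n^2) segment-pair crossing test over non-adjacent closed-polygon edges.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1 & !(i == 1 & j == n)
  }), arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(FALSE)
  i <- pairs[, 1]; j <- pairs[, 2]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Circular-equivalent lumen from a perimeter
#'
#' The section-level lumen rule: diameter and area are always derived from
#' the measured luminal perimeter assuming a circular shape, `d = P / pi`
#' and `A = P^2 / (4 pi)`. Because embedding compresses the wall without
#' shortening it, the perimeter survives deformation that planimetric area
#' does not, making this the robust estimator for collapsed sections.
#'
#' @param perimeter Positive perimeter(s), mm.
#' @return A tibble with `circ_diameter` (mm) and `lumen_area` (mm^2).
#' @export
lumen_from_perimeter <- function(perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive", call. = FALSE)
  tibble::tibble(circ_diameter = perimeter / pi,
                 lumen_area = perimeter^2 / (4 * pi))
}

#' Lumen area of a diseased section by plaque subtraction
#'
#' For sections with plaque, the pre-disease lumen circle is reconstructed
#' from the perimeter of the inner layer of the tunica media, and the
#' measured plaque area is subtracted from that circle's area. Negative
#' results (plaque annotated larger than the reconstructed circle) clamp to
#' zero with a near-occlusion warning.
#'
#' @param media_perimeter Perimeter of the inner-media boundary, mm (> 0).
#' @param plaque_area Planimetric plaque area, mm^2 (>= 0).
#' @return Lumen area(s) in mm^2.
#' @export
lumen_with_plaque <- function(media_perimeter, plaque_area) {
  if (any(media_perimeter <= 0)) stop("media perimeter must be positive", call. = FALSE)
  if (any(plaque_area < 0)) stop("plaque area must be >= 0", call. = FALSE)
  lumen <- media_perimeter^2 / (4 * pi) - plaque_area
  if (any(lumen < 0)) {
    warn("plaque area exceeds the reconstructed media circle; lumen clamped to 0 (near-occlusion)")
    lumen <- pmax(lumen, 0)
  }
  lumen
}

#' Measure histology sections
#'
#' Applies the section-level morphometry to a contour table (one row per
#' contour, as produced by [virtual_histology()] or [read_sections()]):
#' planimetry of each contour, then the perimeter rule. Sections whose
#' media contour carries a positive plaque area use the plaque-subtraction
#' rule on the media perimeter; all others use the lumen contour directly.
#'
#' @param sections Tibble with `vessel_id`, `section_id`, `position_mm`,
#'   `role` (`"lumen"`/`"media"`), `contour` (list of n x 2 matrices, mm)
#'   and `plaque_area_mm2`.
#' @return A tibble with one row per section: `vessel_id`, `side` (when
#'   present), `section_id`, `position_mm`, `perimeter_mm`,
#'   `planimetric_area_mm2`, `circ_diameter_mm`, `lumen_area_mm2`,
#'   `used_plaque_rule`.
#' @export
measure_sections <- function(sections) {
  stopifnot(all(c("vessel_id", "section_id", "position_mm", "role", "contour")
                %in% names(sections)))
  if (!"plaque_area_mm2" %in% names(sections)) sections$plaque_area_mm2 <- 0
  sections |>
    dplyr::group_by(.data$vessel_id, .data$section_id) |>
    dplyr::group_modify(function(g, key) {
      plaque <- max(g$plaque_area_mm2[g$role == "media"], 0)
      use_plaque <- plaque > 0 && any(g$role == "media")
      row <- if (use_plaque) g[g$role == "media", ][1, ]
             else if (any(g$role == "lumen")) g[g$role == "lumen", ][1, ]
             else g[1, ]
      pm <- polygon_metrics(row$contour[[1]])
      lumen <- if (use_plaque) lumen_with_plaque(pm$perimeter, plaque)
               else lumen_from_perimeter(pm$perimeter)$lumen_area
      out <- tibble::tibble(position_mm = row$position_mm,
                            perimeter_mm = pm$perimeter,
                            planimetric_area_mm2 = pm$planimetric_area,
                            circ_diameter_mm = pm$perimeter / pi,
                            lumen_area_mm2 = lumen,
                            used_plaque_rule = use_plaque)
      if ("side" %in% names(row)) out <- dplyr::mutate(out, side = row$side, .before = 1)
      out
    }) |>
    dplyr::ungroup()
}

#' Nine-segment lumen profile from histology sections
#'
#' When a vessel has exactly `n_segments` sections, section k maps directly
#' to segment k (the index-matched design of cutting every 500 microns
#' along a normalized vessel). Otherwise positions are normalized to [0, 1]
#' and each section is assigned to the nearest of `n_segments` equidistant
#' bin centers; segments left without a section carry `NA`.
#'
#' @param measurements Output of [measure_sections()] for one or more
#'   vessels, ordered by position within vessel.
#' @param n_segments Number of segments (default 9).
#' @param timepoint_days Label carried into the profile.
#' @return A `lumen_profile` tibble (`vessel_id`, `side`, `timepoint_days`,
#'   `segment`, `mean_diameter_mm`, `area_mm2`) where the diameter is the
#'   circular equivalent of the segment's mean lumen area.
#' @export
histology_profile <- function(measurements, n_segments = 9L, timepoint_days = NA_real_) {
  stopifnot(all(c("vessel_id", "position_mm", "lumen_area_mm2") %in% names(measurements)))
  measurements |>
    dplyr::group_by(.data$vessel_id) |>
    dplyr::group_modify(function(g, key) {
      if (anyDuplicated(g$position_mm))
        stop("duplicate section positions for vessel ", key$vessel_id, call. = FALSE)
      g <- dplyr::arrange(g, .data$position_mm)
      if (nrow(g) == n_segments) {
        seg <- seq_len(n_segments)
      } else {
        rngp <- range(g$position_mm)
        t <- if (diff(rngp) == 0) rep(0.5, nrow(g))
             else (g$position_mm - rngp[1]) / diff(rngp)
        seg <- pmin(pmax(round(t * n_segments + 0.5), 1L), n_segments)
      }
      area <- vapply(seq_len(n_segments), function(i) {
        v <- g$lumen_area_mm2[seg == i]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, numeric(1))
      side <- if ("side" %in% names(g)) g$side[1] else NA_character_
      tibble::tibble(side = side, timepoint_days = timepoint_days,
                     segment = seq_len(n_segments),
                     mean_diameter_mm = sqrt(4 * area / pi),
                     area_mm2 = area)
    }) |>
    dplyr::ungroup() -> out
  class(out) <- c("lumen_profile", class(out))
  out
}

#' Write / read histology section contours as CSV
#'
#' One row per contour with the polygon serialized as a WKT-style string
#' (`POLYGON ((x y, x y, ...))`). Vertex units are declared in the `units`
#' column and converted to mm on load (supported: `mm`, `um`).
#'
#' @param sections Contour tibble (see [measure_sections()] for columns).
#' @param path CSV path.
#' @param units Units the vertices are written in (`"mm"` or `"um"`).
#' @return `path` (write) / contour tibble in mm (read).
#' @export
write_sections <- function(sections, path, units = "mm") {
  scale <- switch(units, mm = 1, um = 1000,
                  stop("unsupported units: ", units, call. = FALSE))
  df <- sections |>
    dplyr::mutate(
      polygon = vapply(.data$contour, function(m) {
        m <- m * scale
        paste0("POLYGON ((",
               paste(sprintf("%.12g %.12g", m[, 1], m[, 2]), collapse = ", "),
               "))")
      }, character(1)),
      units = units) |>
    dplyr::select(-"contour")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sections
#' @export
read_sections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"units" %in% names(df)) stop("sections CSV must declare `units`", call. = FALSE)
  scale <- ifelse(df$units == "um", 1 / 1000,
                  ifelse(df$units == "mm", 1, NA_real_))
  if (anyNA(scale)) stop("unsupported units in sections CSV", call. = FALSE)
  contours <- lapply(seq_len(nrow(df)), function(i) {
    body <- sub("^POLYGON \\(\\(", "", sub("\\)\\)$", "", df$polygon[i]))
    verts <- strsplit(strsplit(body, ",\\s*")[[1]], "\\s+")
    m <- do.call(rbind, lapply(verts, as.numeric))
    m * scale[i]
  })
  tibble::as_tibble(df[setdiff(names(df), c("polygon", "units"))]) |>
    dplyr::mutate(contour = contours)
}
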