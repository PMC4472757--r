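#' Bin a diameter trace into the standardized nine-segment lumen profile
#'
#' Normalizes arc length to [0, 1], partitions it into `n_segments`
#' equidistant parts (segment 1 at the aortic-arch end, segment
#' `n_segments` at the bifurcation), averages the sampled diameters within
#' each part, and converts each mean diameter to a circular cross-section
#' area `pi * d^2 / 4`. Normalizing length before binning is what makes
#' profiles comparable across animals with different carotid lengths.
#'
#' @param profile A data frame with `arc_mm` (strictly increasing) and
#'   `diameter_mm`, e.g. from [diameter_profile()].
#' @param n_segments Number of equidistant segments (default 9, matching
#'   sections cut every 500 microns along a ~4.2 mm carotid).
#' @param vessel_id,side,timepoint_days Labels carried into the output.
#' @return A `lumen_profile` tibble: `vessel_id`, `side`, `timepoint_days`,
#'   `segment`, `mean_diameter_mm`, `area_mm2`.
#' @export
bin_profile <- function(profile, n_segments = 9L, vessel_id = "V1",
                        side = "LCCA", timepoint_days = NA_real_) {
  stopifnot(all(c("arc_mm", "diameter_mm") %in% names(profile)))
  arc <- profile$arc_mm
  dia <- profile$diameter_mm
  if (length(arc) < n_segments)
    stop("need at least ", n_segments, " samples to fill ", n_segments,
         " segments", call. = FALSE)
  if (any(diff(arc) <= 0))
    stop("`arc_mm` must be strictly increasing", call. = FALSE)
  t <- (arc - arc[1]) / (arc[length(arc)] - arc[1])
  seg <- pmin(floor(t * n_segments) + 1L, n_segments)
  counts <- tabulate(seg, nbins = n_segments)
  if (any(counts == 0L))
    stop("segment(s) ", paste(which(counts == 0L), collapse = ", "),
         " received no samples; resample the trace more densely before binning",
         call. = FALSE)
  d <- vapply(seq_len(n_segments), function(i) mean(dia[seg == i]), numeric(1))
  out <- tibble::tibble(vessel_id = vessel_id, side = side,
                        timepoint_days = timepoint_days,
                        segment = seq_len(n_segments),
                        mean_diameter_mm = d, area_mm2 = pi * d^2 / 4)
  class(out) <- c("lumen_profile", class(out))
  out
}

#' Average lumen profiles over animals
#'
#' Per-segment mean and standard error of the mean of lumen area over a
#' group of vessels (all of the same side and timepoint).
#'
#' @param profiles A `lumen_profile` tibble holding one or more vessels
#'   (rows stacked), or a list of them.
#' @return A tibble with `segment`, `mean_area_mm2`, `sem_area_mm2`, `n`.
#' @export
group_profile <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- dplyr::bind_rows(profiles)
  stopifnot(all(c("segment", "area_mm2", "vessel_id") %in% names(profiles)))
  if (dplyr::n_distinct(profiles$side) > 1L ||
      dplyr::n_distinct(profiles$timepoint_days) > 1L)
    stop("profiles mix sides or timepoints; group them first", call. = FALSE)
  if (dplyr::n_distinct(profiles$vessel_id) == 1L)
    warn("single vessel in group; SEM reported as 0")
  profiles |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      mean_area_mm2 = mean(.data$area_mm2),
      sem_area_mm2 = if (dplyr::n() > 1L) sd(.data$area_mm2) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop")
}

#' One-way ANOVA across timepoints with Bonferroni pairwise comparisons
#'
#' Tests whether mean lumen area differs across timepoint groups. Each
#' animal contributes one value: the mean area over its profile segments
#' (computed here when `data` still carries per-segment rows). A one-way
#' ANOVA is followed by all pairwise pooled-SD t-tests with Bonferroni
#' adjustment (raw p times the number of comparisons, capped at 1).
#'
#' @param data Either a stacked `lumen_profile` tibble (per-segment rows
#'   with `vessel_id`, `timepoint_days`, `area_mm2`) or a per-animal tibble
#'   with one row per vessel.
#' @param value,group Column names (strings) of the response and grouping
#'   variable; defaults fit profile tibbles.
#' @return A tibble of pairwise comparisons (`group1`, `group2`,
#'   `p_adjusted`) with the overall ANOVA `statistic` (F), `df`, and
#'   `p_overall` as attributes (also returned by [glance()]).
#' @export
timepoint_anova <- function(data, value = "area_mm2", group = "timepoint_days") {
  if (all(c("segment", "vessel_id") %in% names(data)) && "segment" %in% names(data)) {
    data <- data |>
      dplyr::group_by(.data$vessel_id, .data[[group]]) |>
      dplyr::summarise(.value = mean(.data[[value]]), .groups = "drop")
    value <- ".value"
  }
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  within_var <- tapply(y, g, stats::var)
  if (all(within_var == 0))
    stop("zero within-group variance in every group; F statistic is degenerate",
         call. = FALSE)
  fit <- aov(y ~ g)
  tab <- anova(fit)
  pw <- pairwise.t.test(y, g, pool.sd = TRUE, p.adjust.method = "bonferroni")$p.value
  comp <- which(!is.na(pw), arr.ind = TRUE)
  out <- tibble::tibble(
    group1 = rownames(pw)[comp[, 1]],
    group2 = colnames(pw)[comp[, 2]],
    p_adjusted = pw[comp])
  attr(out, "statistic") <- tab$`F value`[1]
  attr(out, "df") <- tab$Df
  attr(out, "p_overall") <- tab$`Pr(>F)`[1]
  class(out) <- c("lumen_anova", class(out))
  out
}

#' @export
print.lumen_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g; Bonferroni pairwise:\n",
              attr(x, "df")[1], attr(x, "df")[2], attr(x, "statistic"),
              attr(x, "p_overall")))
  NextMethod()
}

#' Per-segment two-sample t-tests between two profile groups
#'
#' Compares lumen area segment by segment between two groups of vessels
#' using unpaired, equal-variance (Student) two-sided t-tests. P-values are
#' reported unadjusted, one per segment.
#'
#' @param profiles_a,profiles_b Stacked `lumen_profile` tibbles for the two
#'   groups (>= 2 vessels each).
#' @param value Column to compare, default `"area_mm2"`.
#' @return A tibble with `segment`, `mean_a`, `mean_b`, `statistic` (t),
#'   `p_value`.
#' @export
segment_ttest <- function(profiles_a, profiles_b, value = "area_mm2") {
  segs <- sort(unique(profiles_a$segment))
  purrr::map_dfr(segs, function(s) {
    a <- profiles_a[[value]][profiles_a$segment == s]
    b <- profiles_b[[value]][profiles_b$segment == s]
    if (length(a) < 2L || length(b) < 2L)
      stop("need n >= 2 per group in segment ", s, call. = FALSE)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b))
        return(tibble::tibble(segment = s, mean_a = mean(a), mean_b = mean(b),
                              statistic = 0, p_value = 1))
      stop("zero pooled variance in segment ", s, call. = FALSE)
    }
    tt <- t.test(a, b, var.equal = TRUE)
    tibble::tibble(segment = s, mean_a = mean(a), mean_b = mean(b),
                   statistic = unname(tt$statistic), p_value = tt$p.value)
  })
}
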