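#' Cross-modality linear regression
#'
#' Ordinary least-squares regression of one modality's per-vessel mean
#' lumen area on the other's, with the Pearson correlation and its
#' two-sided p-value (t-test on r with n - 2 degrees of freedom). By
#' default micro-CT (`area_a`) is the response and histology (`area_b`)
#' the predictor; swap the column names to change direction.
#'
#' @param data Data frame of paired per-vessel measurements; positive
#'   areas, one row per vessel.
#' @param response,predictor Column names (strings) of the two modalities.
#' @return A `lumen_agreement` object; see [tidy()] and [glance()].
#' @export
agreement_regression <- function(data, response = "area_a", predictor = "area_b") {
  y <- data[[response]]; x <- data[[predictor]]
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete pairs for regression", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y))
  structure(list(model = fit,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r = unname(ct$estimate), p_value = ct$p.value, n = n,
                 response = response, predictor = predictor,
                 data = tibble::tibble(x = x, y = y)),
            class = "lumen_agreement")
}

#' @export
print.lumen_agreement <- function(x, ...) {
  cat(sprintf("<lumen_agreement> %s ~ %s (n = %d)\n  slope %.4g, intercept %.4g, r = %.3f, p = %.3g\n",
              x$response, x$predictor, x$n, x$slope, x$intercept, x$r, x$p_value))
  invisible(x)
}

#' @export
tidy.lumen_agreement <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = c("(Intercept)", x$predictor),
                 estimate = unname(s[, 1]), std.error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @export
glance.lumen_agreement <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 r.squared = summary(x$model)$r.squared,
                 p.value = x$p_value, n = x$n)
}

#' @export
autoplot.lumen_agreement <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::labs(x = paste(object$predictor, "(mm²)"),
                  y = paste(object$response, "(mm²)"),
                  subtitle = sprintf("slope %.2f, r = %.2f, p = %.2g",
                                     object$slope, object$r, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman agreement analysis
#'
#' Per-vessel differences between the two modalities summarized by their
#' mean (bias) and the limits of agreement, `bias +/- 1.96 * SD` of the
#' differences (sample SD, n - 1 denominator); the limits are expected to
#' contain about 95% of between-method differences.
#'
#' @param data Data frame of paired measurements.
#' @param a,b Column names of the two modalities; differences are `a - b`.
#' @return A one-row `lumen_blandaltman` tibble: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`; the per-pair means and differences are
#'   attached as attribute `pairs` for plotting.
#' @export
bland_altman <- function(data, a = "area_a", b = "area_b") {
  xa <- data[[a]]; xb <- data[[b]]
  keep <- is.finite(xa) & is.finite(xb)
  xa <- xa[keep]; xb <- xb[keep]
  if (length(xa) < 2L)
    stop("Bland-Altman analysis needs at least 2 pairs", call. = FALSE)
  d <- xa - xb
  bias <- mean(d)
  s <- sd(d)
  out <- tibble::tibble(bias = bias, sd_diff = s,
                        loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                        n = length(d))
  attr(out, "pairs") <- tibble::tibble(mean = (xa + xb) / 2, diff = d)
  class(out) <- c("lumen_blandaltman", class(out))
  out
}

#' @export
autoplot.lumen_blandaltman <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "mean of modalities (mm²)",
                  y = "difference (mm²)",
                  subtitle = sprintf("bias %.3g, limits [%.3g, %.3g]",
                                     object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Per-timepoint correlation between modalities
#'
#' Applies [agreement_regression()] within each timepoint group.
#' Undersized groups (fewer than 3 pairs) or groups with a degenerate
#' predictor are skipped with a warning.
#'
#' @param data Paired measurements with a timepoint column.
#' @param response,predictor Modality column names.
#' @param timepoint Grouping column name (default `"timepoint_days"`).
#' @return A tibble with one row per usable timepoint: `timepoint`,
#'   `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
per_timepoint_correlation <- function(data, response = "area_a",
                                      predictor = "area_b",
                                      timepoint = "timepoint_days") {
  groups <- split(data, data[[timepoint]])
  purrr::imap_dfr(groups, function(g, tp) {
    ok <- is.finite(g[[response]]) & is.finite(g[[predictor]])
    if (sum(ok) < 3L || stats::var(g[[predictor]][ok]) == 0) {
      warn(paste0("timepoint ", tp, " skipped: fewer than 3 usable pairs ",
                  "or degenerate predictor"))
      return(NULL)
    }
    fit <- agreement_regression(g, response, predictor)
    tibble::tibble(timepoint = tp, slope = fit$slope, intercept = fit$intercept,
                   r = fit$r, p_value = fit$p_value, n = fit$n)
  })
}

#' Plot a lumen profile
#'
#' Lumen area against segment index, one line per vessel, from the aortic
#' arch (segment 1) to the bifurcation (last segment).
#'
#' @param object A `lumen_profile` tibble (one or more vessels stacked).
#' @param ... Unused.
#' @export
autoplot.lumen_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$segment, y = .data$area_mm2,
                               colour = .data$vessel_id, group = .data$vessel_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = sort(unique(object$segment))) +
    ggplot2::labs(x = "segment (1 = aortic arch)", y = "lumen area (mm²)",
                  colour = "vessel") +
    ggplot2::theme_minimal()
}

#' Plot a group profile with SEM ribbon
#' @param group_prof Output of [group_profile()].
#' @return A ggplot object.
#' @export
plot_group_profile <- function(group_prof) {
  ggplot2::ggplot(group_prof, ggplot2::aes(x = .data$segment, y = .data$mean_area_mm2)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_area_mm2 - .data$sem_area_mm2,
                                      ymax = .data$mean_area_mm2 + .data$sem_area_mm2),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") + ggplot2::geom_point() +
    ggplot2::labs(x = "segment (1 = aortic arch)",
                  y = "mean lumen area ± SEM (mm²)") +
    ggplot2::theme_minimal()
}
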