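constant_trace <- function(d, n = 90, len = 4.2) {
  tibble::tibble(arc_mm = seq(0, len, length.out = n), diameter_mm = d)
}

test_that("constant diameter fills all nine segments with the circular area", {
  pr <- bin_profile(constant_trace(0.3))
  expect_equal(nrow(pr), 9L)
  expect_equal(pr$segment, 1:9)
  expect_equal(pr$mean_diameter_mm, rep(0.3, 9))
  expect_equal(pr$area_mm2, rep(0.070686, 9), tolerance = 1e-5)
  # typical healthy LCCA caliber
  pr2 <- bin_profile(constant_trace(0.328))
  expect_equal(pr2$area_mm2, rep(pi * 0.328^2 / 4, 9), tolerance = 1e-12)
  expect_equal(pr2$area_mm2[1], 0.084496, tolerance = 1e-5)
})

test_that("binned means match an independent per-bin average on a ramp", {
  arc <- seq(0, 4.2, length.out = 900)
  d <- seq(0.2, 0.4, length.out = 900)
  pr <- bin_profile(tibble::tibble(arc_mm = arc, diameter_mm = d))
  t <- arc / max(arc)
  seg <- pmin(floor(t * 9) + 1, 9)
  oracle <- vapply(1:9, function(i) mean(d[seg == i]), numeric(1))
  expect_equal(pr$mean_diameter_mm, oracle)
  expect_equal(pr$area_mm2, pi * oracle^2 / 4)
})

test_that("profile areas scale quadratically under diameter scaling", {
  arc <- seq(0, 4.2, length.out = 200)
  set.seed(3)
  d <- 0.3 + cumsum(rnorm(200, 0, 0.001))
  p1 <- bin_profile(tibble::tibble(arc_mm = arc, diameter_mm = d))
  p2 <- bin_profile(tibble::tibble(arc_mm = arc, diameter_mm = 1.7 * d))
  expect_equal(p2$mean_diameter_mm, 1.7 * p1$mean_diameter_mm)
  expect_equal(p2$area_mm2, 1.7^2 * p1$area_mm2)
})

test_that("sparse or unsorted traces are rejected with guidance", {
  expect_error(bin_profile(tibble::tibble(arc_mm = c(0, 1, 2, 4.2),
                                          diameter_mm = 0.3)),
               "at least 9")
  expect_error(bin_profile(tibble::tibble(arc_mm = c(seq(0, 1, length.out = 10), 0.5),
                                          diameter_mm = 0.3)),
               "strictly increasing")
  # 10 samples clustered at both ends leave interior bins empty
  expect_error(bin_profile(tibble::tibble(
    arc_mm = c(seq(0, 0.05, length.out = 5), seq(4.1, 4.2, length.out = 5)),
    diameter_mm = 0.3)), "no samples")
})

test_that("group profile reports per-segment mean and SEM over animals", {
  p1 <- bin_profile(constant_trace(0.3), vessel_id = "A")
  p2 <- bin_profile(constant_trace(0.3), vessel_id = "B")
  g <- group_profile(dplyr::bind_rows(p1, p2))
  expect_equal(g$mean_area_mm2, p1$area_mm2)
  expect_equal(g$sem_area_mm2, rep(0, 9))
  expect_equal(g$n, rep(2L, 9))

  # two-animal case with areas 1 and 3: mean 2, SEM = SD/sqrt(2) = 1
  pa <- p1; pa$area_mm2 <- rep(1, 9)
  pb <- p2; pb$area_mm2 <- rep(3, 9)
  g2 <- group_profile(dplyr::bind_rows(pa, pb))
  expect_equal(g2$mean_area_mm2, rep(2, 9))
  expect_equal(g2$sem_area_mm2, rep(1, 9))

  expect_warning(group_profile(p1), "single vessel")
  set.seed(11)
  many <- dplyr::bind_rows(lapply(1:10, function(i) {
    p <- bin_profile(constant_trace(0.3), vessel_id = paste0("V", i))
    p$area_mm2 <- p$area_mm2 + rnorm(9, 0, 0.002)
    p
  }))
  g3 <- group_profile(many)
  areas <- matrix(many$area_mm2[order(many$segment)], nrow = 10)
  expect_equal(g3$mean_area_mm2, colMeans(areas))
  expect_equal(g3$sem_area_mm2, apply(areas, 2, sd) / sqrt(10))
})

test_that("identical timepoint groups give F = 0 and adjusted p = 1", {
  d <- tibble::tibble(
    area = rep(c(1.0, 1.1, 0.9, 1.05), 3),
    timepoint_days = rep(c(7, 14, 28), each = 4))
  res <- timepoint_anova(d, value = "area", group = "timepoint_days")
  expect_equal(attr(res, "statistic"), 0, tolerance = 1e-12)
  expect_equal(res$p_adjusted, rep(1, 3))
})

test_that("anova input contracts are enforced", {
  d <- tibble::tibble(area = c(1, 2), timepoint_days = c(7, 14))
  expect_error(timepoint_anova(d, "area", "timepoint_days"), "n >= 2")
  dz <- tibble::tibble(area = rep(c(1, 2), each = 3),
                       timepoint_days = rep(c(7, 14), each = 3))
  dz$area <- rep(c(1, 2), each = 3)  # zero within-group variance
  expect_error(timepoint_anova(dz, "area", "timepoint_days"), "degenerate")
})

test_that("a strong day-28 lumen loss is detected with Bonferroni correction", {
  set.seed(21)
  d <- tibble::tibble(
    area = c(rnorm(9, 1.0, 0.05), rnorm(9, 1.0, 0.05), rnorm(9, 0.5, 0.05)),
    timepoint_days = rep(c(7, 14, 28), each = 9))
  res <- timepoint_anova(d, value = "area", group = "timepoint_days")
  p28 <- res$p_adjusted[res$group1 == "28" | res$group2 == "28"]
  expect_true(all(p28 < 0.001))
  p7_14 <- res$p_adjusted[(res$group1 == "14" & res$group2 == "7") |
                            (res$group1 == "7" & res$group2 == "14")]
  expect_true(all(p7_14 > 0.05))
})

test_that("per-animal means are pooled from profile segments before testing", {
  set.seed(22)
  prof <- dplyr::bind_rows(lapply(1:6, function(i) {
    p <- bin_profile(constant_trace(0.3), vessel_id = paste0("V", i),
                     timepoint_days = c(7, 14, 28)[(i - 1) %/% 2 + 1])
    p$area_mm2 <- p$area_mm2 + rnorm(9, 0, 0.001)
    p
  }))
  res <- timepoint_anova(prof)
  expect_equal(nrow(res), 3L)  # three pairwise comparisons
  expect_true(all(res$p_adjusted >= 0 & res$p_adjusted <= 1))
})

test_that("segment t-test matches the pooled-variance closed form", {
  pa <- dplyr::bind_rows(lapply(1:3, function(i)
    bin_profile(constant_trace(0.3), vessel_id = paste0("A", i))))
  pb <- dplyr::bind_rows(lapply(1:3, function(i)
    bin_profile(constant_trace(0.3), vessel_id = paste0("B", i))))
  pa$area_mm2 <- rep(c(1, 2, 3), each = 9)
  pb$area_mm2 <- rep(c(2, 3, 4), each = 9)
  res <- segment_ttest(pa, pb)
  # hand-computed pooled t for {1,2,3} vs {2,3,4}
  sp <- sqrt((2 * 1 + 2 * 1) / 4)
  t_hand <- (2 - 3) / (sp * sqrt(1 / 3 + 1 / 3))
  p_hand <- 2 * pt(abs(t_hand), df = 4, lower.tail = FALSE)
  expect_equal(res$statistic, rep(t_hand, 9), tolerance = 1e-12)
  expect_equal(res$p_value, rep(p_hand, 9), tolerance = 1e-12)

  # identical groups -> p = 1 everywhere
  res0 <- segment_ttest(pa, pa)
  expect_equal(res0$p_value, rep(1, 9))
})

test_that("a two-SD shift is reliably detected per segment", {
  set.seed(23)
  hits <- 0; reps <- 100
  for (r in 1:reps) {
    a <- rnorm(10, 0, 1); b <- rnorm(10, 2, 1)
    pa <- tibble::tibble(segment = 1, area_mm2 = a)
    pb <- tibble::tibble(segment = 1, area_mm2 = b)
    if (segment_ttest(pa, pb)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})
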