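regular_polygon <- function(n, r = 0.5) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(t), r * sin(t))
}

test_that("planimetry of canonical shapes is exact", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m <- polygon_metrics(sq)
  expect_identical(m$perimeter, 4)
  expect_identical(m$planimetric_area, 1)

  # 256-gon inscribed in a circle of radius 0.5
  m2 <- polygon_metrics(regular_polygon(256))
  expect_lt(abs(m2$perimeter - pi) / pi, 1e-3)
  expect_lt(abs(m2$planimetric_area - pi / 4) / (pi / 4), 1e-3)

  # orientation invariance
  m3 <- polygon_metrics(sq[4:1, ])
  expect_identical(m3, m)
})

test_that("invalid contours are rejected or warned", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_metrics(bowtie), "self-intersecting")
  expect_error(polygon_metrics(rbind(c(0, 0), c(1, 1))), "n >= 3")
  degen <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_warning(polygon_metrics(degen), "zero area")
})

test_that("perimeter rule gives the circular-equivalent diameter and area", {
  r <- lumen_from_perimeter(pi)
  expect_equal(r$circ_diameter, 1, tolerance = 1e-12)
  expect_equal(r$lumen_area, pi / 4, tolerance = 1e-12)

  # unit square read through the circular assumption: area 4/pi > 1,
  # quantifying the convexification bias of the rule
  sq <- lumen_from_perimeter(4)
  expect_equal(sq$circ_diameter, 4 / pi, tolerance = 1e-12)
  expect_equal(sq$lumen_area, 4 / pi, tolerance = 1e-12)
  expect_gt(sq$lumen_area, 1)
  expect_error(lumen_from_perimeter(0), "positive")
})

test_that("perimeter rule undoes embedding compression on phantom sections", {
  v <- vessel_spec(rbind(c(0, 0, 0), c(4.2, 0, 0)), base_diameter = 0.3,
                   length = 4.2)
  sc <- scene_spec(v, rng_seed = 1)
  sec <- virtual_histology(sc, histology_artefacts(shrink_factor = 1,
                                                   compression_ratio = 2,
                                                   rng_seed = 1))
  meas <- measure_sections(sec)
  true_area <- pi * (sec$true_diameter_mm[sec$role == "lumen"] / 2)^2
  expect_true(all(abs(meas$lumen_area_mm2 - true_area) / true_area < 0.01))
  # while raw planimetry of the compressed ellipse falls well short
  expect_true(all(meas$planimetric_area_mm2 < 0.95 * true_area))
})

test_that("plaque subtraction reduces the media circle and clamps at zero", {
  p <- 2 * sqrt(pi * 0.10)  # media circle of area exactly 0.10 mm^2
  expect_equal(p, 1.12100, tolerance = 1e-5)
  expect_equal(lumen_with_plaque(p, 0.03), 0.07, tolerance = 1e-12)
  expect_equal(lumen_with_plaque(p, 0), lumen_from_perimeter(p)$lumen_area)
  expect_warning(res <- lumen_with_plaque(p, 0.2), "clamped")
  expect_identical(res, 0)
  expect_error(lumen_with_plaque(0, 0.1), "positive")
})

test_that("circular-assumption area dominates planimetric area (isoperimetry)", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(8:40, 1)
    ang <- sort(runif(n, 0, 2 * pi))
    rad <- runif(n, 0.3, 1)
    poly <- cbind(rad * cos(ang), rad * sin(ang))  # star-shaped, simple
    m <- polygon_metrics(poly)
    expect_gte(lumen_from_perimeter(m$perimeter)$lumen_area,
               m$planimetric_area)
  }
})

test_that("linear shrink scales measured lumen areas by exactly f^2", {
  poly <- regular_polygon(64, 0.2)
  f <- 0.77
  a1 <- lumen_from_perimeter(polygon_metrics(poly)$perimeter)$lumen_area
  a2 <- lumen_from_perimeter(polygon_metrics(poly * f)$perimeter)$lumen_area
  expect_equal(a2, f^2 * a1, tolerance = 1e-12)
})

test_that("nine sections map index-to-segment; equal areas give a flat profile", {
  sec <- tibble::tibble(
    vessel_id = "V1", section_id = 1:9, position_mm = seq(0, 4, by = 0.5),
    role = "lumen",
    contour = lapply(1:9, function(i) regular_polygon(64, 0.15)),
    plaque_area_mm2 = 0)
  meas <- measure_sections(sec)
  prof <- histology_profile(meas)
  expect_equal(nrow(prof), 9L)
  expect_equal(prof$segment, 1:9)
  expect_equal(diff(range(prof$area_mm2)), 0)
  expect_equal(prof$area_mm2, pi * prof$mean_diameter_mm^2 / 4, tolerance = 1e-12)
})

test_that("uncompressed unshrunken histology matches the phantom truth profile", {
  # healthy vessel: the segment profile is flat, so point sections and bin
  # means coincide and any disagreement is measurement error
  sc <- small_test_scene(diameter = 0.3, length_mm = 4.2, seed = 4, severity = 0)
  sec <- virtual_histology(sc, histology_artefacts(shrink_factor = 1,
                                                   section_spacing = 0.5,
                                                   rng_seed = 2))
  prof <- histology_profile(measure_sections(sec))
  truth <- build_phantom(sc)$truth_profile
  expect_true(all(abs(prof$area_mm2 - truth$area_mm2) / truth$area_mm2 < 0.05))

  # stenosed vessel: each section recovers the pointwise true lumen area
  sc2 <- small_test_scene(diameter = 0.3, length_mm = 4.2, seed = 4)
  sec2 <- virtual_histology(sc2, histology_artefacts(shrink_factor = 1,
                                                     section_spacing = 0.5,
                                                     rng_seed = 2))
  meas2 <- measure_sections(sec2)
  truth_pt <- sec2$true_area_mm2[sec2$role == "lumen"]
  expect_true(all(abs(meas2$lumen_area_mm2 - truth_pt) / truth_pt < 0.01))
})

test_that("a lost section falls back to nearest-bin assignment", {
  pos <- seq(0, 4, by = 0.5)[-4]  # section 4 lost
  sec <- tibble::tibble(
    vessel_id = "V1", section_id = seq_along(pos), position_mm = pos,
    role = "lumen",
    contour = lapply(seq_along(pos), function(i) regular_polygon(64, 0.1 + 0.01 * i)),
    plaque_area_mm2 = 0)
  meas <- measure_sections(sec)
  prof <- histology_profile(meas)
  # oracle: independent nearest-center assignment on normalized positions
  t <- (pos - min(pos)) / diff(range(pos))
  centers <- (1:9 - 0.5) / 9
  seg_oracle <- vapply(t, function(ti) which.min(abs(ti - centers)), integer(1))
  areas <- vapply(1:9, function(s) {
    v <- meas$lumen_area_mm2[seg_oracle == s]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  expect_equal(prof$area_mm2, areas)
  expect_equal(sum(is.na(prof$area_mm2)), 1L)
})

test_that("duplicate section positions are rejected", {
  sec <- tibble::tibble(
    vessel_id = "V1", section_id = 1:2, position_mm = c(0, 0), role = "lumen",
    contour = lapply(1:2, function(i) regular_polygon(16, 0.1)),
    plaque_area_mm2 = 0)
  expect_error(histology_profile(measure_sections(sec)), "duplicate")
})

test_that("sections survive a WKT CSV round trip, including unit conversion", {
  sec <- tibble::tibble(
    vessel_id = "V1", side = "LCCA", section_id = 1:2,
    position_mm = c(0, 0.5), role = "lumen",
    contour = list(regular_polygon(16, 0.15), regular_polygon(16, 0.12)),
    plaque_area_mm2 = c(0, 0.01))
  path <- tempfile(fileext = ".csv")
  write_sections(sec, path, units = "um")
  back <- read_sections(path)
  expect_equal(back$vessel_id, sec$vessel_id)
  for (i in 1:2)
    expect_equal(back$contour[[i]], unname(sec$contour[[i]]), tolerance = 1e-9)
})
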