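test_that("vessel and scene specs enforce their invariants", {
  expect_error(vessel_spec(rbind(c(0, 0, 0), c(0, 0, 0))), "duplicate")
  expect_error(vessel_spec(rbind(c(0, 0, 0), c(1, 0, 0)), base_diameter = 0),
               "positive")
  expect_error(vessel_spec(rbind(c(0, 0, 0), c(1, 0, 0)),
                           stenoses = data.frame(position = 0.5, severity = 1,
                                                 extent = 0.1)),
               "never fully occluded")
  expect_error(vessel_spec(rbind(c(0, 0, 0), c(1, 0, 0)),
                           stenoses = data.frame(position = 0, severity = 0.4,
                                                 extent = 0.1)),
               "strictly inside")
  v <- vessel_spec(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(scene_spec(v, intensity_blood = 90, intensity_muscle = 100),
               "blood > muscle > background")
  expect_error(scene_spec(v, noise_sd = -1), "noise_sd")
})

test_that("noise-free unblurred tube renders blood intensity exactly in its core", {
  v <- vessel_spec(rbind(c(0, 0, 0), c(1.0, 0, 0)), base_diameter = 10 * 0.018)
  sc <- scene_spec(v, psf_sigma = 0, noise_sd = 0, rng_seed = 1)
  ph <- build_phantom(sc)
  vol <- ph$volume
  d <- dim(vol)
  # voxels whose center is deeper than one voxel inside the tube
  ijk <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  w <- sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  inside_x <- w[, 1] >= 0 & w[, 1] <= 1.0
  rad <- sqrt(w[, 2]^2 + w[, 3]^2)
  core <- inside_x & rad <= (5 - 1.01) * 0.018
  expect_gt(sum(core), 100)
  expect_true(all(vol$intensities[ijk[core, ]] == sc$intensity_blood))
})

test_that("blood ROI of the default scene recovers the configured blood intensity", {
  sc <- small_test_scene(diameter = 0.3, seed = 11)
  ph <- build_phantom(sc)
  idx <- lumenprof:::roi_indices(ph$volume, ph$blood_roi)
  m <- mean(ph$volume$intensities[idx])
  sem <- sc$noise_sd / sqrt(length(idx))
  # blur correlates neighbouring noise samples, so allow 3 nominal SEM + the
  # sub-unit residual the kernel leaves on a 64-voxel interior box
  expect_lt(abs(m - 148.3), 3 * sem + 0.5)
})

test_that("stenosis narrows the true diameter to base * (1 - severity)", {
  v <- vessel_spec(rbind(c(0, 0, 0), c(4.2, 0, 0)), base_diameter = 0.328,
                   stenoses = data.frame(position = 0.5, severity = 0.4,
                                         extent = 0.1))
  sc <- scene_spec(v, rng_seed = 1)
  ph <- build_phantom(sc)
  tr <- ph$truth
  d_mid <- stats::approx(tr$arc_mm / max(tr$arc_mm), tr$diameter_mm, xout = 0.5)$y
  expect_equal(d_mid, 0.328 * 0.6, tolerance = 1e-3)
  expect_equal(min(tr$diameter_mm), 0.328 * 0.6, tolerance = 1e-3)
})

test_that("identical scene specs render bit-identical volumes and sections", {
  sc1 <- small_test_scene(seed = 5)
  sc2 <- small_test_scene(seed = 5)
  p1 <- build_phantom(sc1); p2 <- build_phantom(sc2)
  expect_identical(p1$volume$intensities, p2$volume$intensities)
  art <- histology_artefacts(rng_seed = 3)
  expect_identical(virtual_histology(sc1, art), virtual_histology(sc2, art))
  # and a different noise seed changes the volume
  p3 <- build_phantom(small_test_scene(seed = 6))
  expect_false(identical(p1$volume$intensities, p3$volume$intensities))
})

test_that("above-threshold volume of a clean tube matches the analytic solid", {
  # generic alignment: a radius of exactly 5 voxels on a lattice-aligned axis
  # is a Gauss-circle worst case with 12 lattice points on the surface
  r_mm <- 5.3 * 0.018
  len <- 1.2
  v <- vessel_spec(rbind(c(0, 0.007, 0.004), c(len, 0.007, 0.004)),
                   base_diameter = 2 * r_mm)
  sc <- scene_spec(v, psf_sigma = 0, noise_sd = 0, rng_seed = 1)
  ph <- build_phantom(sc)
  thr <- sc$intensity_background + 0.5 * (sc$intensity_blood - sc$intensity_background)
  vol_meas <- sum(ph$volume$intensities >= thr) * prod(sc$voxel_size)
  # rendered solid = tube + 1.5 r stumps + hemispherical end caps
  vol_true <- pi * r_mm^2 * (len + 3 * r_mm) + (4 / 3) * pi * r_mm^3
  expect_lt(abs(vol_meas - vol_true) / vol_true, 0.05)
})

test_that("stored truth profile equals independent arc-length binning", {
  sc <- small_test_scene(seed = 2)
  ph <- build_phantom(sc)
  tr <- ph$truth
  t <- tr$arc_mm / max(tr$arc_mm)
  seg <- pmin(floor(t * 9) + 1, 9)
  d_oracle <- vapply(1:9, function(i) mean(tr$diameter_mm[seg == i]), numeric(1))
  expect_equal(ph$truth_profile$diameter_mm, d_oracle)
  expect_equal(ph$truth_profile$area_mm2, pi * d_oracle^2 / 4)
})

test_that("vessels that do not fit the requested grid are rejected", {
  v <- vessel_spec(rbind(c(0, 0, 0), c(2, 0, 0)), base_diameter = 0.3)
  sc <- scene_spec(v, dim = c(20, 20, 20), rng_seed = 1)
  expect_error(build_phantom(sc), "fit|bounds")
})

test_that("virtual histology cuts sections at the configured spacing", {
  v <- vessel_spec(rbind(c(0, 0, 0), c(4.2, 0, 0)), base_diameter = 0.328,
                   length = 4.2)
  sc <- scene_spec(v, rng_seed = 1)
  sec <- virtual_histology(sc, histology_artefacts(section_spacing = 0.5,
                                                   rng_seed = 1))
  expect_equal(dplyr::n_distinct(sec$section_id), 9L)
  expect_equal(sort(unique(sec$position_mm)), seq(0, 4, by = 0.5))
  # spacing beyond the vessel length degrades to a single warned section
  expect_warning(
    sec1 <- virtual_histology(sc, histology_artefacts(section_spacing = 10,
                                                      rng_seed = 1)),
    "single section")
  expect_equal(unique(sec1$position_mm), 0)
})

test_that("shrink scales section perimeter by f and area by f^2", {
  v <- vessel_spec(rbind(c(0, 0, 0), c(4.2, 0, 0)), base_diameter = 0.3,
                   length = 4.2)
  sc <- scene_spec(v, rng_seed = 1)
  f <- 0.77
  sec_f <- virtual_histology(sc, histology_artefacts(shrink_factor = f, rng_seed = 1))
  sec_1 <- virtual_histology(sc, histology_artefacts(shrink_factor = 1, rng_seed = 1))
  m_f <- polygon_metrics(sec_f$contour[[1]])
  m_1 <- polygon_metrics(sec_1$contour[[1]])
  expect_equal(m_f$perimeter, f * m_1$perimeter, tolerance = 1e-9)
  expect_equal(m_f$planimetric_area, f^2 * m_1$planimetric_area, tolerance = 1e-9)
})

test_that("compression preserves perimeter but reduces planimetric area", {
  v <- vessel_spec(rbind(c(0, 0, 0), c(4.2, 0, 0)), base_diameter = 0.3,
                   length = 4.2)
  sc <- scene_spec(v, rng_seed = 1)
  sec <- virtual_histology(sc, histology_artefacts(shrink_factor = 1,
                                                   compression_ratio = 2,
                                                   rng_seed = 1))
  m <- polygon_metrics(sec$contour[[1]])
  r <- sec$true_diameter_mm[1] / 2
  # oracle: ellipse perimeter by independent quadrature on the a = 2b shape
  quad <- integrate(function(t) sqrt(4 * sin(t)^2 + cos(t)^2), 0, 2 * pi,
                    rel.tol = 1e-10)$value
  b <- 2 * pi * r / quad
  expect_equal(m$perimeter, 2 * pi * r, tolerance = 5e-3)  # equal-perimeter build
  expect_lt(m$planimetric_area, pi * r^2)
  expect_equal(m$planimetric_area, pi * (2 * b) * b, tolerance = 1e-3)
})

test_that("plaque area is the configured fraction of the shrunken media circle", {
  v <- vessel_spec(rbind(c(0, 0, 0), c(4.2, 0, 0)), base_diameter = 0.3,
                   length = 4.2)
  sc <- scene_spec(v, rng_seed = 1)
  art <- histology_artefacts(shrink_factor = 0.8, plaque_fraction = 0.3,
                             rng_seed = 1)
  sec <- virtual_histology(sc, art)
  media <- sec[sec$role == "media", ]
  expect_equal(media$plaque_area_mm2,
               0.3 * pi * (media$true_diameter_mm / 2 * 0.8)^2,
               tolerance = 1e-12)
  expect_true(all(sec$plaque_area_mm2[sec$role == "lumen"] == 0))
})
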