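test_that("both centerline extractors track a straight tube to sub-voxel accuracy", {
  sm <- cyl_phantom(r = 5)
  cl_t <- centerline_aorta(sm$mask)
  expect_lt(rms_off_axis(cl_t), 0.5)
  pa <- suppressWarnings(centerline_pa(sm$mask))
  expect_lt(rms_off_axis(pa$centerline), 0.5)
  expect_equal(nrow(pa$branch_points), 0)
  # the two methods agree along the shared extent
  expect_lt(abs(mean(cl_t$points[, 1]) - mean(pa$centerline$points[, 1])), 1)
  # tangents are unit-norm and arclength strictly increases
  expect_equal(rowSums(cl_t$tangents^2), rep(1, nrow(cl_t$tangents)),
               tolerance = 1e-9)
  expect_true(all(diff(cl_t$arclength) > 0))
})

test_that("the arch tracker recovers the analytic arc length", {
  sm <- arch_phantom(r = 4)
  cl <- centerline_aorta(sm$mask)
  expect_equal(max(cl$arclength), pi * 15, tolerance = 0.05)
})

test_that("a single-voxel mask leaves no eroded core to track", {
  m <- array(0, dim = c(16, 16, 16)); m[8, 8, 8] <- 1
  expect_error(centerline_aorta(ct_volume(m, intensity_kind = "mask")),
               "erosion")
  expect_error(centerline_aorta(ct_volume(m * 0, intensity_kind = "mask")),
               "empty")
})

test_that("the Y-tree skeleton finds exactly one branch point at the bifurcation", {
  sm <- tree_phantom(r = 4)
  pa <- centerline_pa(sm$mask)
  expect_equal(nrow(pa$branch_points), 1)
  true_bif <- sm$truth$anchors$bifurcation
  expect_lt(sqrt(sum((pa$branch_points[1, ] - true_bif)^2)), 2)
  # smoothing never lengthens the skeleton path
  expect_lte(max(pa$centerline$arclength), pa$raw_length_mm + 1e-6)
})

test_that("perpendicular cross-sections of a cylinder recover the true diameter", {
  sm <- cyl_phantom(r = 5)
  cs <- cross_section(sm$mask, c(31.5, 31.5, 30), c(0, 0, 1))
  expect_equal(cs$equivalent_diameter_mm, 10, tolerance = 0.1)
  expect_equal(cs$equivalent_diameter_mm, 2 * sqrt(cs$area_mm2 / pi),
               tolerance = 1e-12)
  # tilting the plane 60 degrees off-axis inflates the area by 1/cos(60)
  tilt <- c(sin(pi / 3), 0, cos(pi / 3))
  cs60 <- cross_section(sm$mask, c(31.5, 31.5, 30), tilt, max_radius_mm = 25)
  expect_equal(cs60$area_mm2, pi * 25 / cos(pi / 3), tolerance = 0.06)
  expect_error(cross_section(sm$mask, c(2, 2, 2), c(0, 0, 1)), "outside")
})

test_that("the cross-section plane basis is orthogonal to the tangent", {
  ob <- vesselct:::orthonormal_basis(c(0.3, -0.5, 0.81))
  expect_lt(abs(sum(ob$u * ob$normal)), 1e-9)
  expect_lt(abs(sum(ob$v * ob$normal)), 1e-9)
  expect_lt(abs(sum(ob$u * ob$v)), 1e-9)
})

test_that("mean diameter over the aorta window recovers a 10 mm cylinder", {
  sm <- cyl_phantom(r = 5)
  cl <- centerline_aorta(sm$mask)
  rep <- mean_diameter(sm$mask, cl, c(5, 25), 0.4, "aorta")
  expect_equal(nrow(rep$sections), floor((25 - 5) / 0.4) + 1)  # 51 sections
  expect_equal(rep$mean_diameter_mm, 10, tolerance = 1)
  expect_equal(rep$mean_diameter_mm, mean(rep$sections$equivalent_diameter_mm),
               tolerance = 1e-12)
  single <- mean_diameter(sm$mask, cl, c(10, 10), 0.4, "aorta")
  expect_equal(nrow(single$sections), 1)
  expect_error(mean_diameter(sm$mask, cl, c(5, 500), 0.4), "arclength")
  expect_error(mean_diameter(sm$mask, cl, c(5, 25), -1), "positive")
})

test_that("curvature does not bias the torus-arch diameter", {
  sm <- arch_phantom(r = 4)
  cl <- centerline_aorta(sm$mask)
  rep <- mean_diameter(sm$mask, cl, c(5, 25), 0.4, "aorta")
  expect_equal(rep$mean_diameter_mm, 8, tolerance = 1)
})

test_that("the PA window measured from the branch point recovers the trunk diameter", {
  sm <- tree_phantom(r = 4)
  pa <- centerline_pa(sm$mask)
  rep <- mean_diameter(sm$mask, pa$centerline, c(5, 15), 0.4, "pulmonary_artery")
  expect_equal(rep$mean_diameter_mm, 8, tolerance = 1)
  expect_equal(nrow(rep$sections), floor((15 - 5) / 0.4) + 1)
})

test_that("diameter estimates preserve the ordering of tube radii", {
  d <- vapply(c(3, 4, 5), function(r) {
    sm <- cyl_phantom(r = r, seed = 40 + r)
    cl <- centerline_aorta(sm$mask, erosion_radius = 1.5)
    mean_diameter(sm$mask, cl, c(5, 25), 0.4, "aorta")$mean_diameter_mm
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("reports serialize to JSON and CSV", {
  sm <- cyl_phantom(r = 5)
  cl <- centerline_aorta(sm$mask)
  rep <- mean_diameter(sm$mask, cl, c(10, 12), 0.4, "aorta")
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_diameter_report(rep, jp, cp)
  j <- jsonlite::read_json(jp)
  expect_equal(j$mean_diameter_mm, rep$mean_diameter_mm, tolerance = 1e-9)
  csv <- read.csv(cp)
  expect_equal(nrow(csv), nrow(rep$sections))
  unlink(c(jp, cp))
})

test_that("the PA/Ao ratio behaves like a ratio", {
  expect_equal(pa_ao_ratio(25, 25), 1)
  expect_equal(pa_ao_ratio(24, 30), 0.8)
  expect_equal(pa_ao_ratio(17, 23) * pa_ao_ratio(23, 17), 1, tolerance = 1e-12)
  expect_error(pa_ao_ratio(20, 0), "positive")
})
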