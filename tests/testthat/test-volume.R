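test_that("HU windowing maps the window endpoints and midpoint exactly", {
  v <- ct_volume(array(c(-160, 240, 40, -1000, 1000, 0), dim = c(3, 2, 1)),
                 intensity_kind = "HU")
  w <- window_normalize(v)
  expect_equal(w$data[1, 1, 1], 0)
  expect_equal(w$data[2, 1, 1], 1)
  expect_equal(w$data[3, 1, 1], 0.5)
  expect_equal(w$data[1, 2, 1], 0)  # clipped below
  expect_equal(w$data[2, 2, 1], 1)  # clipped above
  expect_identical(w$intensity_kind, "normalized")
  expect_error(window_normalize(v, 100, 100), "lo < hi")
  expect_error(window_normalize(w), "HU")
})

test_that("windowing is idempotent on re-expressed normalized values", {
  set.seed(1)
  v <- ct_volume(array(runif(60, -160, 240), dim = c(5, 4, 3)),
                 intensity_kind = "HU")
  w1 <- window_normalize(v)
  # re-express the normalized volume in HU and window again
  back <- ct_volume(w1$data * 400 - 160, spacing = v$spacing,
                    intensity_kind = "HU")
  w2 <- window_normalize(back)
  expect_equal(w2$data, w1$data, tolerance = 1e-12)
})

test_that("identity and constant resampling are exact", {
  set.seed(2)
  v <- ct_volume(array(rnorm(8 * 6 * 4), dim = c(8, 6, 4)),
                 spacing = c(2, 2, 2), intensity_kind = "HU")
  r <- resample_volume(v, c(2, 2, 2))
  expect_identical(r$data, v$data)
  cv <- ct_volume(array(7, dim = c(8, 6, 4)), spacing = c(2, 1, 3),
                  intensity_kind = "HU")
  r2 <- resample_volume(cv, 1)
  expect_true(all(r2$data == 7))
  expect_equal(dim(r2$data), c(16L, 6L, 12L))
  expect_equal(mean(r2$data), mean(cv$data))  # conserves the mean exactly
})

test_that("resampling a linear ramp matches the analytic ramp", {
  ramp <- array(rep(0:9 * 2, times = 100), dim = c(10, 10, 10))  # 2 HU per voxel in x
  v <- ct_volume(ramp, spacing = c(2, 2, 2), intensity_kind = "HU")
  r <- resample_volume(v, 1, order = 1L)
  expect_equal(dim(r$data), c(20L, 20L, 20L))
  # voxel i of the output sits at input coordinate (i-1)/2, value (i-1)
  interior <- 1:19  # the last voxel clamps at the input border
  expect_equal(r$data[interior, 1, 1], as.numeric(interior - 1),
               tolerance = 1e-6)
  expect_error(resample_volume(v, -1), "positive")
})

test_that("nearest-neighbour resampling keeps masks binary", {
  m <- ct_volume(array(rbinom(8^3, 1, 0.4), dim = c(8, 8, 8)),
                 spacing = c(2, 2, 2), intensity_kind = "mask")
  r <- resample_volume(m, 1.3, order = 0L)
  expect_true(all(r$data %in% c(0, 1)))
})

test_that("VOI extraction matches direct slicing at the interior", {
  set.seed(3)
  v <- ct_volume(array(rnorm(40^3), dim = c(40, 40, 40)),
                 intensity_kind = "HU")
  spec <- voi_spec(c(20, 20, 20), "pulmonary_artery", shape = c(16, 16, 8))
  voi <- extract_voi(v, spec)
  expect_equal(dim(voi$data), c(16L, 16L, 8L))
  expect_identical(voi$data, v$data[12:27, 12:27, 16:23])
})

test_that("corner VOI padding equals the analytic overlap", {
  v <- ct_volume(array(1, dim = c(20, 20, 20)), intensity_kind = "HU")
  spec <- voi_spec(c(2, 2, 2), "pulmonary_artery", shape = c(8, 8, 8))
  voi <- extract_voi(v, spec, pad_value = 0)
  # brute-force membership count: source voxels covered by the crop
  start <- c(2, 2, 2) - 4
  inside <- 0
  for (i in 0:7) for (j in 0:7) for (k in 0:7) {
    s <- start + c(i, j, k)
    if (all(s >= 1) && all(s <= 20)) inside <- inside + 1
  }
  expect_equal(sum(voi$data), inside)
  expect_equal(mean(voi$data == 0), 1 - inside / 512)
  expect_error(extract_voi(v, voi_spec(c(0, 5, 5), shape = c(4, 4, 4))),
               "outside")
})

test_that("VOI paste-back restores exactly the in-bounds voxels", {
  set.seed(4)
  v <- ct_volume(array(rnorm(24^3), dim = c(24, 24, 24)), intensity_kind = "HU")
  spec <- voi_spec(c(12, 12, 12), shape = c(8, 8, 8))
  voi <- extract_voi(v, spec)
  back <- paste_voi(voi)
  expect_equal(dim(back$data), dim(v$data))
  expect_identical(back$data[8:15, 8:15, 8:15], voi$data)
  re <- extract_voi(back, spec)
  expect_identical(re$data, voi$data)  # extract -> paste -> extract round trip
})

test_that("default VOI shapes follow the vessel target", {
  expect_equal(voi_spec(c(1, 1, 1), "aorta")$shape, c(128L, 128L, 64L))
  expect_equal(voi_spec(c(1, 1, 1), "pulmonary_artery")$shape, c(96L, 96L, 32L))
})

test_that("NIfTI volumes round-trip through disk", {
  set.seed(5)
  v <- ct_volume(array(rnorm(10 * 12 * 8), dim = c(10, 12, 8)),
                 spacing = c(0.7, 0.7, 2), origin = c(-5, 3, 10),
                 intensity_kind = "HU")
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(v, path)
  r <- read_nifti_volume(path)
  expect_equal(r$data, v$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-5)
  unlink(path)
})

test_that("voxel/world coordinate transforms invert each other", {
  v <- ct_volume(array(0, dim = c(5, 5, 5)), spacing = c(0.5, 1, 2),
                 origin = c(10, -4, 2), intensity_kind = "HU")
  idx <- rbind(c(1, 1, 1), c(3, 4, 5))
  xyz <- voxel_to_world(v, idx)
  expect_equal(xyz[1, ], c(10, -4, 2))
  expect_equal(world_to_voxel(v, xyz), idx, ignore_attr = TRUE)
})

test_that("volume invariants are enforced", {
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  expect_error(ct_volume(array(2, c(2, 2, 2)), intensity_kind = "normalized"),
               "\\[0, 1\\]")
  expect_error(ct_volume(array(0.5, c(2, 2, 2)), intensity_kind = "mask"),
               "binary")
})
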