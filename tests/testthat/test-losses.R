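test_that("mean absolute error matches an element-loop oracle", {
  set.seed(10)
  a <- array(runif(4 * 3 * 5), dim = c(4, 3, 5))
  b <- array(runif(4 * 3 * 5), dim = c(4, 3, 5))
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, a + 0.1), 0.1, tolerance = 1e-12)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  expect_equal(mae(a, b), acc / length(a), tolerance = 1e-12)
  expect_equal(mae(a, b, reduce = "sum"), acc, tolerance = 1e-12)
  expect_error(mae(a, array(0, c(2, 2, 2))), "shape")
})

test_that("SSIM is 1 for identical images and symmetric", {
  set.seed(11)
  a <- array(runif(9^3), dim = c(9, 9, 9))
  b <- array(runif(9^3), dim = c(9, 9, 9))
  expect_equal(ssim3d(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim3d(a, b), ssim3d(b, a), tolerance = 1e-12)
  expect_error(ssim3d(array(0, c(3, 3, 3)), array(0, c(3, 3, 3)),
                      loss_config(ssim_window = 7)), "larger")
})

test_that("SSIM of two constants equals the closed-form stabilized value", {
  a <- array(0, dim = c(9, 9, 9))
  b <- array(1, dim = c(9, 9, 9))
  cfg <- loss_config()
  C1 <- (cfg$ssim_k1 * cfg$data_range)^2
  C2 <- (cfg$ssim_k2 * cfg$data_range)^2
  # mu_a = 0, mu_b = 1, all variances zero:
  closed <- ((2 * 0 * 1 + C1) * (0 + C2)) / ((0 + 1 + C1) * (0 + C2))
  expect_equal(ssim3d(a, b, cfg), closed, tolerance = 1e-12)
})

test_that("anti-correlated structure yields negative SSIM", {
  idx <- expand.grid(x = 1:10, y = 1:10, z = 1:10)
  a <- array(as.numeric((idx$x + idx$y + idx$z) %% 2), dim = c(10, 10, 10))
  expect_lt(ssim3d(a, 1 - a), 0)
})

test_that("DSSIM is (1 - SSIM)/2 with the expected endpoints", {
  set.seed(12)
  a <- array(runif(9^3), dim = c(9, 9, 9))
  b <- array(runif(9^3), dim = c(9, 9, 9))
  expect_equal(dssim(a, a), 0, tolerance = 1e-12)
  expect_equal(dssim(a, b), (1 - ssim3d(a, b)) / 2, tolerance = 1e-12)
})

test_that("the composite loss mixes MAE and DSSIM as specified", {
  set.seed(13)
  a <- array(runif(9^3), dim = c(9, 9, 9))
  b <- array(runif(9^3), dim = c(9, 9, 9))
  expect_equal(combined_loss(a, a), 0, tolerance = 1e-12)
  expect_equal(combined_loss(a, b, loss_config(alpha = 1)), mae(a, b),
               tolerance = 1e-12)
  m <- mae(a, b); d <- dssim(a, b)
  for (al in c(0, 0.3, 0.7, 1))
    expect_equal(combined_loss(a, b, loss_config(alpha = al)),
                 al * m + (1 - al) * d, tolerance = 1e-12)
  # monotone in alpha between its two component values
  vals <- vapply(seq(0, 1, by = 0.25), function(al)
    combined_loss(a, b, loss_config(alpha = al)), numeric(1))
  expect_true(all(diff(vals) > 0) || all(diff(vals) < 0))
  expect_true(all(vals >= min(m, d) - 1e-12 & vals <= max(m, d) + 1e-12))
})

test_that("the worked alpha = 0.7 arithmetic holds", {
  # mae 0.1 and dssim 0.2 combine to 0.7*0.1 + 0.3*0.2 = 0.13
  expect_equal(0.7 * 0.1 + (1 - 0.7) * 0.2, 0.13)
})

test_that("the SSIM gradient matches finite differences", {
  set.seed(14)
  a <- array(runif(8^3), dim = c(8, 8, 8))
  b <- array(runif(8^3), dim = c(8, 8, 8))
  cfg <- loss_config()
  sg <- vesselct:::ssim3d_grad(a, b, cfg)
  expect_equal(sg$value, ssim3d(a, b, cfg), tolerance = 1e-12)
  for (i in sample(length(a), 5)) {
    a1 <- a; a1[i] <- a1[i] + 1e-5
    a2 <- a; a2[i] <- a2[i] - 1e-5
    num <- (ssim3d(a1, b, cfg) - ssim3d(a2, b, cfg)) / 2e-5
    expect_equal(sg$grad[i], num, tolerance = 1e-6)
  }
})

test_that("soft Dice follows the squared-denominator formula", {
  p <- array(c(1, 1, 0), dim = c(3, 1, 1))
  g <- array(c(1, 0, 1), dim = c(3, 1, 1))
  expect_equal(dice_coefficient(p, g, smooth = 0), 0.5)
  m <- array(rbinom(27, 1, 0.5), dim = c(3, 3, 3))
  m[1] <- 1
  expect_equal(dice_coefficient(m, m, smooth = 0), 1)
  expect_equal(dice_coefficient(array(c(1, 0), c(2, 1, 1)),
                                array(c(0, 1), c(2, 1, 1)), smooth = 0), 0)
  expect_equal(dice_loss(m, m, smooth = 0), 0)
  expect_error(dice_coefficient(m, array(0, c(2, 2, 2))), "shape")
})

test_that("binary DSC equals a set-arithmetic oracle on random mask pairs", {
  set.seed(15)
  for (rep in 1:100) {
    a <- array(rbinom(64, 1, runif(1, 0.1, 0.9)), dim = c(4, 4, 4))
    b <- array(rbinom(64, 1, runif(1, 0.1, 0.9)), dim = c(4, 4, 4))
    A <- which(a == 1); B <- which(b == 1)
    oracle <- if (length(A) + length(B) == 0) 1 else
      2 * length(intersect(A, B)) / (length(A) + length(B))
    expect_identical(dsc_binary(a, b), oracle)
    # smooth-free soft Dice coincides with it on binary data
    expect_equal(dice_coefficient(a, b, smooth = 0),
                 ifelse(is.nan(2 * sum(a * b) / (sum(a) + sum(b))), NaN, oracle),
                 tolerance = 1e-12)
  }
  z <- array(0, dim = c(4, 4, 4))
  expect_equal(dsc_binary(z, z), 1)  # both empty
  d1 <- z; d1[1] <- 1
  expect_equal(dsc_binary(d1, z), 0)
  expect_error(dsc_binary(z + 0.5, z), "binary")
})

test_that("a DSC of 0.9 arises from 90 shared voxels of two 100-voxel masks", {
  a <- array(0, dim = c(10, 10, 10)); b <- a
  a[1:100] <- 1
  b[11:110] <- 1  # |A| = |B| = 100, overlap 90
  expect_equal(dsc_binary(a, b), 2 * 90 / 200)
})

test_that("Dice loss gradient matches finite differences", {
  set.seed(16)
  p <- array(runif(4^3), dim = c(4, 4, 4))
  g <- array(rbinom(64, 1, 0.4), dim = c(4, 4, 4))
  lg <- vesselct:::dice_loss_grad(p, g, smooth = 1e-6)
  expect_equal(lg$value, dice_loss(p, g, smooth = 1e-6), tolerance = 1e-12)
  for (i in sample(64, 5)) {
    p1 <- p; p1[i] <- p1[i] + 1e-6
    p2 <- p; p2[i] <- p2[i] - 1e-6
    num <- (dice_loss(p1, g, 1e-6) - dice_loss(p2, g, 1e-6)) / 2e-6
    expect_equal(lg$grad[i], num, tolerance = 1e-5)
  }
})
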