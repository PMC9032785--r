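tiny_pair <- function(seed = 3, grid = 32) {
  sm <- render_phantom(phantom_spec("straight_tube", grid_shape = rep(grid, 3),
                                    tube_radius_mm = 5, seed = seed))
  list(nc = window_normalize(sm$nc), ce = window_normalize(sm$ce),
       mask = sm$mask$data)
}

test_that("enhancement training reduces the composite loss", {
  p <- tiny_pair()
  cfg <- train_config(learning_rate = 3e-3, epochs = 12, batch_size = 1,
                      seed = 5, patches_per_epoch = 3)
  net <- net_config(depth = 2, base_filters = 4, dropout_rate = 0)
  m <- train_enhancement(list(list(nc = p$nc, ce = p$ce)), cfg, net)
  h <- attr(m, "history")
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_identical(m$stage, "enhancement")
})

test_that("the identity task drives the loss toward zero", {
  p <- tiny_pair(seed = 6)
  cfg <- train_config(learning_rate = 3e-3, epochs = 25, batch_size = 1,
                      seed = 7, patches_per_epoch = 3)
  net <- net_config(depth = 2, base_filters = 4, dropout_rate = 0)
  m <- train_enhancement(list(list(nc = p$nc, ce = p$nc)), cfg, net)
  y <- enhance(p$nc, m)
  expect_lt(mae(y$data, p$nc$data), 0.06)
  expect_true(all(y$data > 0 & y$data < 1))
})

test_that("training is reproducible from the seed", {
  p <- tiny_pair(seed = 8)
  cfg <- train_config(learning_rate = 3e-3, epochs = 5, batch_size = 1,
                      seed = 99, patches_per_epoch = 2)
  net <- net_config(depth = 2, base_filters = 2, dropout_rate = 0.1)
  m1 <- train_enhancement(list(list(nc = p$nc, ce = p$ce)), cfg, net)
  m2 <- train_enhancement(list(list(nc = p$nc, ce = p$ce)), cfg, net)
  expect_equal(attr(m1, "history"), attr(m2, "history"), tolerance = 1e-12)
  expect_equal(m1$params, m2$params, tolerance = 1e-12)
})

test_that("enhance() rejects a non-enhancement bundle and mismatched pairs error early", {
  set.seed(33)
  seg <- build_unet3d(net_config(depth = 1, base_filters = 2))
  seg$stage <- "final"
  expect_error(enhance(array(0.5, c(8, 8, 8)), seg), "stage")
  p <- tiny_pair(seed = 9, grid = 16)
  broken <- list(list(nc = p$nc, ce = window_normalize(
    render_phantom(phantom_spec("straight_tube", grid_shape = c(24, 24, 24),
                                seed = 1))$ce)))
  expect_error(train_enhancement(broken, train_config(epochs = 1)), "grids differ")
})

test_that("segmentation training raises held-out DSC on an easy phantom task", {
  set.seed(34)
  phs <- generate_phantoms(9, phantom_spec("straight_tube",
                                           grid_shape = c(32, 32, 32)),
                           jitter = list(tube_radius_mm = c(4, 6)), seed = 21)
  ss <- lapply(phs, function(p) {
    v <- window_normalize(p$nc)
    list(x = array(v$data, dim = c(dim(v$data), 1L)), mask = p$mask$data)
  })
  cfg <- train_config(learning_rate = 3e-3, epochs = 35, batch_size = 1,
                      seed = 41, patches_per_epoch = 3)
  net <- net_config(depth = 2, base_filters = 4, dropout_rate = 0)
  m <- train_segmentation(ss[1:8], cfg, init = "fresh", net = net)
  d <- dsc_binary(predict_mask(ss[[9]]$x, m), ss[[9]]$mask)
  expect_gt(d, 0.9)
})

test_that("init schemes validate their inputs", {
  ss <- list(list(x = array(0.5, c(16, 16, 16, 1)),
                  mask = array(0, c(16, 16, 16))))
  expect_error(train_segmentation(ss, train_config(epochs = 1),
                                  init = "encoder_transfer"),
               "enhancement")
  expect_error(train_segmentation(ss, train_config(epochs = 1),
                                  init = "dual_concat"),
               "seg_pretrain")
  set.seed(35)
  enh <- build_unet3d(net_config(depth = 2, base_filters = 2, dropout_rate = 0))
  pre <- build_unet3d(net_config(depth = 2, base_filters = 2, dropout_rate = 0))
  # single-channel samples fed to the two-channel dual model
  expect_error(train_segmentation(ss, train_config(epochs = 1),
                                  init = "dual_concat", enhancement = enh,
                                  seg_pretrain = pre),
               "channel")
})

test_that("mask prediction thresholds and keeps the largest component", {
  set.seed(36)
  m <- build_unet3d(net_config(depth = 1, base_filters = 2, dropout_rate = 0))
  m$params <- lapply(m$params, function(p) p * 0)
  m$params$head_b <- 0.5  # sigmoid(0.5) ~ 0.62 everywhere
  x <- array(runif(8^3), dim = c(8, 8, 8))
  expect_true(all(predict_mask(x, m, threshold = 0.5) == 1))
  expect_true(all(predict_mask(x, m, threshold = 0.7) == 0))
  expect_error(predict_mask(x, m, threshold = 1.2), "threshold")
  # constructed two-blob map: only the larger blob survives
  blobs <- array(0, dim = c(10, 10, 10))
  blobs[2:5, 2:5, 2:5] <- 1    # 64 voxels
  blobs[8:9, 8:9, 8:9] <- 1    # 8 voxels
  kept <- keep_largest_component(blobs)
  expect_equal(sum(kept), 64)
  expect_true(all(kept[8:9, 8:9, 8:9] == 0))
})

test_that("fold plans partition the samples with near-equal sizes", {
  f <- fold_plan(10, 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  expect_identical(f, fold_plan(10, 5, seed = 2))
  f2 <- fold_plan(11, 5, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(fold_plan(3, 5), "exceeds")
})

test_that("cross-validation aggregates per-fold DSC as mean and sd", {
  s <- cv_summary(c(1, 1, 1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  set.seed(37)
  phs <- generate_phantoms(10, phantom_spec("straight_tube",
                                            grid_shape = c(16, 16, 16),
                                            tube_radius_mm = 4),
                           jitter = list(), seed = 31)
  ss <- lapply(phs, function(p) {
    v <- window_normalize(p$nc)
    list(x = array(v$data, dim = c(dim(v$data), 1L)), mask = p$mask$data)
  })
  cfg <- train_config(learning_rate = 3e-3, epochs = 2, batch_size = 2, seed = 51)
  res <- crossvalidate(ss, 5, cfg,
                       net = net_config(depth = 1, base_filters = 2,
                                        dropout_rate = 0))
  expect_length(res$per_fold, 5)
  expect_true(all(table(res$assignment) == 2))  # each sample tested once
  res2 <- crossvalidate(ss, 5, cfg,
                        net = net_config(depth = 1, base_filters = 2,
                                         dropout_rate = 0))
  expect_identical(res$assignment, res2$assignment)
  expect_equal(res$per_fold, res2$per_fold, tolerance = 1e-12)
})
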