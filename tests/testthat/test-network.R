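test_that("forward pass honors the shape/range contract", {
  set.seed(20)
  m <- build_unet3d(net_config(depth = 2, base_filters = 4, dropout_rate = 0))
  x <- array(runif(16^3), dim = c(16, 16, 16))
  y <- unet_forward(m, x)
  expect_equal(dim(y), c(16L, 16L, 16L))
  expect_true(all(y > 0 & y < 1))
  expect_error(unet_forward(m, array(0, c(10, 10, 10))), "divisible")
})

test_that("all-zero weights produce a constant sigmoid(0) = 0.5 output", {
  set.seed(21)
  m <- build_unet3d(net_config(depth = 1, base_filters = 2, dropout_rate = 0))
  m$params <- lapply(m$params, function(p) p * 0)
  y <- unet_forward(m, array(runif(8^3), dim = c(8, 8, 8)))
  expect_true(all(y == 0.5))
})

test_that("parameter count matches a layer-by-layer hand count", {
  set.seed(22)
  m <- build_unet3d(net_config(depth = 1, base_filters = 2, in_channels = 1,
                               dropout_rate = 0))
  hand <- (27 * 1 * 2 + 2) +  # enc1 conv1
    (27 * 2 * 2 + 2) +        # enc1 conv2
    (27 * 2 * 4 + 4) +        # bottleneck conv1 (2 -> 4)
    (27 * 4 * 4 + 4) +        # bottleneck conv2
    (8 * 4 * 2 + 2) +         # transposed up-convolution (4 -> 2)
    (27 * 4 * 2 + 2) +        # dec1 conv1 on concat (2 skip + 2 up -> 2)
    (27 * 2 * 2 + 2) +        # dec1 conv2
    (1 * 2 * 1 + 1)           # 1x1x1 sigmoid head
  expect_equal(count_params(m), hand)
})

test_that("evaluation-mode forward is deterministic even with dropout", {
  set.seed(23)
  m <- build_unet3d(net_config(depth = 2, base_filters = 4, dropout_rate = 0.25))
  x <- array(runif(16^3), dim = c(16, 16, 16))
  expect_identical(unet_forward(m, x), unet_forward(m, x))
})

test_that("encoder transfer copies exactly the selected levels", {
  set.seed(24)
  cfg <- net_config(depth = 2, base_filters = 4, dropout_rate = 0)
  src <- build_unet3d(cfg)
  dst <- build_unet3d(cfg)
  dst0 <- dst
  out <- transfer_encoder(src, dst, levels = integer(0))
  expect_identical(out$params, dst0$params)  # empty level set: unchanged
  out <- transfer_encoder(src, dst)
  for (nm in vesselct:::encoder_layer_names(2))
    expect_identical(out$params[[nm]], src$params[[nm]])
  # non-encoder layers keep the fresh initialization
  expect_identical(out$params$head_w, dst0$params$head_w)
  expect_identical(out$params$bot_conv1_w, dst0$params$bot_conv1_w)
  bad <- build_unet3d(net_config(depth = 2, base_filters = 8, dropout_rate = 0))
  expect_error(transfer_encoder(src, bad), "mismatch")
})

test_that("transferred weights change the forward behaviour", {
  set.seed(25)
  cfg <- net_config(depth = 2, base_filters = 4, dropout_rate = 0)
  src <- build_unet3d(cfg)
  dst <- build_unet3d(cfg)
  x <- array(runif(16^3), dim = c(16, 16, 16))
  y0 <- unet_forward(dst, x)
  y1 <- unet_forward(transfer_encoder(src, dst), x)
  expect_false(isTRUE(all.equal(y0, y1)))
})

test_that("the dual-encoder model initializes both streams from their bundles", {
  set.seed(26)
  cfg <- net_config(depth = 2, base_filters = 4, dropout_rate = 0)
  pre <- build_unet3d(cfg)
  enh <- build_unet3d(cfg)
  dual <- concat_dual_encoder(pre, enh)
  expect_identical(dual$params$sA_enc1_conv1_w, pre$params$enc1_conv1_w)
  expect_identical(dual$params$sB_enc1_conv1_w, enh$params$enc1_conv1_w)
  expect_identical(dual$params$head_w, pre$params$head_w)
  expect_identical(dual$params$dec1_conv2_w, pre$params$dec1_conv2_w)
  expect_identical(dual$stage, "segmentation_pretrain")
  deeper <- build_unet3d(net_config(depth = 3, base_filters = 4, dropout_rate = 0))
  expect_error(concat_dual_encoder(pre, deeper), "mismatch")
})

test_that("with a zero second channel the dual output ignores stream B weights", {
  set.seed(27)
  cfg <- net_config(depth = 2, base_filters = 2, dropout_rate = 0)
  dual <- concat_dual_encoder(build_unet3d(cfg), build_unet3d(cfg))
  x <- array(0, dim = c(16, 16, 16, 2))
  x[, , , 1] <- runif(16^3)
  y1 <- unet_forward(dual, x)
  dual$params$sB_enc1_conv1_w <- dual$params$sB_enc1_conv1_w * 3 + 1
  dual$params$sB_enc2_conv2_w <- dual$params$sB_enc2_conv2_w - 2
  y2 <- unet_forward(dual, x)
  expect_identical(y1, y2)
})

test_that("the dual model maps a two-channel PA-sized VOI to a same-size mask", {
  set.seed(28)
  cfg <- net_config(depth = 2, base_filters = 2, in_channels = 2,
                    dropout_rate = 0)
  dual <- build_unet3d(cfg, dual = TRUE)
  x <- array(runif(96 * 96 * 32 * 2), dim = c(96, 96, 32, 2))
  y <- unet_forward(dual, x)
  expect_equal(dim(y), c(96L, 96L, 32L))
  expect_true(all(y > 0 & y < 1))
})

test_that("checkpoints round-trip bitwise", {
  set.seed(29)
  m <- build_unet3d(net_config(depth = 2, base_filters = 4))
  m$stage <- "enhancement"
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  r <- load_checkpoint(path)
  expect_identical(r$params, m$params)
  expect_identical(r$cfg, m$cfg)
  expect_identical(r$stage, "enhancement")
  unlink(path)
})

test_that("analytic gradients match finite differences through the whole net", {
  set.seed(30)
  m <- build_unet3d(net_config(depth = 2, base_filters = 2, dropout_rate = 0))
  x <- array(runif(8^3), dim = c(8, 8, 8, 1))
  tgt <- array(rbinom(512, 1, 0.3), dim = c(8, 8, 8))
  fw <- unet_forward(m, x, train = TRUE)
  lg <- vesselct:::dice_loss_grad(fw$y, tgt, 1e-6)
  gr <- unet_backward(m, fw$cache, lg$grad)
  loss_of <- function(model) {
    y <- unet_forward(model, x)
    vesselct:::dice_loss_grad(y, tgt, 1e-6)$value
  }
  for (nm in c("enc1_conv1_w", "bot_conv2_b", "dec2_up_w", "dec1_conv1_w",
               "head_w")) {
    i <- sample(length(m$params[[nm]]), 1)
    m1 <- m; m1$params[[nm]][i] <- m1$params[[nm]][i] + 1e-6
    m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] - 1e-6
    num <- (loss_of(m1) - loss_of(m2)) / 2e-6
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("nearest-neighbour upsampling variant runs and learns shapes", {
  set.seed(31)
  m <- build_unet3d(net_config(depth = 2, base_filters = 2, dropout_rate = 0,
                               upsample = "nearest"))
  x <- array(runif(16^3), dim = c(16, 16, 16))
  y <- unet_forward(m, x)
  expect_equal(dim(y), c(16L, 16L, 16L))
  fw <- unet_forward(m, as.array(array(x, c(16, 16, 16, 1))), train = TRUE)
  gr <- unet_backward(m, fw$cache,
                      vesselct:::dice_loss_grad(fw$y, round(x), 1e-6)$grad)
  expect_true(all(c("dec1_proj_w", "dec2_proj_w") %in% names(gr)))
})
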