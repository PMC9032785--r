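#' 3D U-Net configuration
#'
#' Describes the encoder-decoder used by both pipeline stages: `depth`
#' downsampling levels, two 3x3x3 convolutions + ReLU per level with spatial
#' (channel-wise) dropout, 2x2x2 max-pool downsampling, a symmetric decoder
#' with stride-2 upsampling and skip concatenation, and a 1x1x1 sigmoid
#' output head. Filter counts double per level from `base_filters`.
#'
#' @param in_channels input channels (1; 2 for the dual-encoder model built
#'   by [concat_dual_encoder()]).
#' @param depth number of downsampling levels; input grids must be divisible
#'   by `2^depth` on every axis.
#' @param base_filters filters at the first level.
#' @param kernel convolution kernel extent (cubic; default 3).
#' @param dropout_rate spatial dropout rate in \[0, 1) applied to each
#'   encoder block and the bottleneck during training.
#' @param upsample `"transposed"` (learned 2x2x2 transposed convolution) or
#'   `"nearest"` (fixed nearest-neighbour upsampling followed by a learned
#'   3x3x3 projection).
#' @return A `net_config` object.
#' @export
net_config <- function(in_channels = 1L, depth = 3L, base_filters = 8L,
                       kernel = 3L, dropout_rate = 0.25,
                       upsample = c("transposed", "nearest")) {
  upsample <- match.arg(upsample)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (depth < 1) stop("depth must be >= 1")
  if (kernel %% 2 == 0) stop("kernel must be odd")
  structure(list(in_channels = as.integer(in_channels), depth = as.integer(depth),
                 base_filters = as.integer(base_filters), kernel = as.integer(kernel),
                 dropout_rate = dropout_rate, upsample = upsample),
            class = "net_config")
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

init_conv <- function(k, cin, cout) {
  w <- array(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
             dim = c(k, k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

init_upconv <- function(cin, cout) {
  w <- array(stats::rnorm(8 * cin * cout, 0, sqrt(2 / (8 * cin))),
             dim = c(2, 2, 2, cin, cout))
  list(w = w, b = numeric(cout))
}

# identity transposed-convolution weights for nearest-neighbour upsampling
identity_up_w <- function(c) {
  w <- array(0, dim = c(2, 2, 2, c, c))
  for (ci in seq_len(c)) w[, , , ci, ci] <- 1
  w
}

level_filters <- function(cfg, l) cfg$base_filters * 2L^(l - 1L)

# channels entering decoder level l from below
below_channels <- function(cfg, l) {
  if (l == cfg$depth) cfg$base_filters * 2L^cfg$depth else level_filters(cfg, l + 1L)
}

init_stream_encoder <- function(cfg, prefix, in_ch) {
  P <- list()
  for (l in seq_len(cfg$depth)) {
    f <- level_filters(cfg, l)
    cin <- if (l == 1L) in_ch else level_filters(cfg, l - 1L)
    c1 <- init_conv(cfg$kernel, cin, f)
    c2 <- init_conv(cfg$kernel, f, f)
    P[[paste0(prefix, "enc", l, "_conv1_w")]] <- c1$w
    P[[paste0(prefix, "enc", l, "_conv1_b")]] <- c1$b
    P[[paste0(prefix, "enc", l, "_conv2_w")]] <- c2$w
    P[[paste0(prefix, "enc", l, "_conv2_b")]] <- c2$b
  }
  P
}

init_decoder <- function(cfg, skip_mult) {
  # skip_mult = 1 for single-stream, 2 for dual-stream skips
  P <- list()
  for (l in seq_len(cfg$depth)) {
    f <- level_filters(cfg, l)
    cb <- below_channels(cfg, l)
    if (cfg$upsample == "transposed") {
      up <- init_upconv(cb, f)
      P[[paste0("dec", l, "_up_w")]] <- up$w
      P[[paste0("dec", l, "_up_b")]] <- up$b
      cat_in <- f * (skip_mult + 1L)
    } else {
      pr <- init_conv(cfg$kernel, cb, f)
      P[[paste0("dec", l, "_proj_w")]] <- pr$w
      P[[paste0("dec", l, "_proj_b")]] <- pr$b
      cat_in <- f * (skip_mult + 1L)
    }
    c1 <- init_conv(cfg$kernel, cat_in, f)
    c2 <- init_conv(cfg$kernel, f, f)
    P[[paste0("dec", l, "_conv1_w")]] <- c1$w
    P[[paste0("dec", l, "_conv1_b")]] <- c1$b
    P[[paste0("dec", l, "_conv2_w")]] <- c2$w
    P[[paste0("dec", l, "_conv2_b")]] <- c2$b
  }
  P
}

#' Build a 3D U-Net
#'
#' Initializes all parameters (He initialization, zero biases) from the
#' current RNG state; call `set.seed()` first for reproducible builds. The
#' returned model doubles as a weights bundle: the named parameter arrays
#' plus the configuration and a stage-of-origin tag.
#'
#' @param cfg a [net_config()].
#' @param dual build the dual-encoder two-channel variant (normally done via
#'   [concat_dual_encoder()]).
#' @return A `unet3d` model object: `list(cfg, params, stage)`.
#' @export
build_unet3d <- function(cfg, dual = FALSE) {
  P <- list()
  fb <- cfg$base_filters * 2L^cfg$depth  # bottleneck filters
  fd <- level_filters(cfg, cfg$depth)
  if (dual) {
    if (cfg$in_channels != 2L) stop("dual model requires in_channels = 2")
    P <- c(P, init_stream_encoder(cfg, "sA_", 1L), init_stream_encoder(cfg, "sB_", 1L))
    b1 <- init_conv(cfg$kernel, 2L * fd, fb)
  } else {
    P <- c(P, init_stream_encoder(cfg, "", cfg$in_channels))
    b1 <- init_conv(cfg$kernel, fd, fb)
  }
  b2 <- init_conv(cfg$kernel, fb, fb)
  P$bot_conv1_w <- b1$w; P$bot_conv1_b <- b1$b
  P$bot_conv2_w <- b2$w; P$bot_conv2_b <- b2$b
  P <- c(P, init_decoder(cfg, if (dual) 2L else 1L))
  hd <- init_conv(1L, cfg$base_filters, 1L)
  P$head_w <- hd$w; P$head_b <- hd$b
  structure(list(cfg = cfg, params = P, dual = dual, stage = "fresh"),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  cat(sprintf("<unet3d%s> depth %d, base %d, in_channels %d, %s params, stage: %s\n",
              if (x$dual) " dual" else "", x$cfg$depth, x$cfg$base_filters,
              x$cfg$in_channels, format(count_params(x), big.mark = ","), x$stage))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model a `unet3d`.
#' @return Integer count.
#' @export
count_params <- function(model) sum(vapply(model$params, length, numeric(1)))

as_4d <- function(x) {
  if (inherits(x, "ct_volume")) x <- x$data
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

check_divisible <- function(d, depth) {
  if (any(d[1:3] %% 2L^depth != 0L))
    stop("input grid (", paste(d[1:3], collapse = ","),
         ") not divisible by 2^depth = ", 2L^depth)
}

concat_ch <- function(...) {
  xs <- list(...)
  d3 <- dim(xs[[1]])[1:3]
  ctot <- sum(vapply(xs, function(x) dim(x)[4], numeric(1)))
  out <- array(unlist(xs, use.names = FALSE), dim = c(d3, ctot))
  out
}

drop_mask <- function(C, rate) {
  keep <- stats::runif(C) >= rate
  if (!any(keep)) keep[sample.int(C, 1L)] <- TRUE  # never drop every channel
  as.numeric(keep) / (1 - rate)
}

apply_channel_scale <- function(x, scale) {
  x * rep(scale, each = prod(dim(x)[1:3]))
}

# forward through one encoder stream; returns list(skips, pooled caches, out)
stream_forward <- function(P, cfg, prefix, x, train) {
  sk <- list(); cache <- list()
  cur <- x
  for (l in seq_len(cfg$depth)) {
    g <- function(nm) P[[paste0(prefix, "enc", l, "_", nm)]]
    x_in <- cur
    a1 <- relu(conv3d_fw(x_in, g("conv1_w"), g("conv1_b"), cfg$kernel))
    a2 <- relu(conv3d_fw(a1, g("conv2_w"), g("conv2_b"), cfg$kernel))
    dm <- NULL
    if (train && cfg$dropout_rate > 0) {
      dm <- drop_mask(dim(a2)[4], cfg$dropout_rate)
      a2 <- apply_channel_scale(a2, dm)
    }
    pl <- maxpool3d_fw(a2)
    cache[[l]] <- list(x_in = x_in, a1 = a1, a2 = a2, dm = dm,
                       pool_idx = pl$idx, a2_dim = dim(a2))
    sk[[l]] <- a2
    cur <- pl$out
  }
  list(skips = sk, cache = cache, out = cur)
}

stream_backward <- function(P, cfg, prefix, cache, d_pool, d_skips, grads) {
  # d_pool: grad at the deepest pooled output; iterate levels depth..1
  for (l in rev(seq_len(cfg$depth))) {
    cc <- cache[[l]]
    g <- function(nm) paste0(prefix, "enc", l, "_", nm)
    d_a2 <- maxpool3d_bw(d_pool, cc$pool_idx, cc$a2_dim)
    if (!is.null(d_skips[[l]])) d_a2 <- d_a2 + d_skips[[l]]
    if (!is.null(cc$dm)) d_a2 <- apply_channel_scale(d_a2, cc$dm)
    dz2 <- d_a2 * (cc$a2 > 0)
    bw2 <- conv3d_bw(cc$a1, P[[g("conv2_w")]], dz2, cfg$kernel)
    grads[[g("conv2_w")]] <- bw2$dw; grads[[g("conv2_b")]] <- bw2$db
    dz1 <- bw2$dx * (cc$a1 > 0)
    bw1 <- conv3d_bw(cc$x_in, P[[g("conv1_w")]], dz1, cfg$kernel)
    grads[[g("conv1_w")]] <- bw1$dw; grads[[g("conv1_b")]] <- bw1$db
    d_pool <- bw1$dx
  }
  grads
}

#' Forward pass of a U-Net model
#'
#' @param model a `unet3d`.
#' @param x input array `(X, Y, Z)` or `(X, Y, Z, C)` (or a `ct_volume`);
#'   grid must be divisible by `2^depth`.
#' @param train if `TRUE`, applies spatial dropout (from the current RNG
#'   state) and returns the activation cache needed by the backward pass.
#'   Evaluation mode (`FALSE`, default) is deterministic.
#' @return `train = FALSE`: the sigmoid output array `(X, Y, Z)`.
#'   `train = TRUE`: `list(y, cache)`.
#' @export
unet_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg; P <- model$params
  x <- as_4d(x)
  check_divisible(dim(x), cfg$depth)
  if (dim(x)[4] != cfg$in_channels)
    stop("expected ", cfg$in_channels, " input channel(s), got ", dim(x)[4])
  cache <- list()
  if (model$dual) {
    d3 <- dim(x)[1:3]
    xa <- array(x[, , , 1L], dim = c(d3, 1L))
    xb <- array(x[, , , 2L], dim = c(d3, 1L))
    sA <- stream_forward(P, cfg, "sA_", xa, train)
    sB <- stream_forward(P, cfg, "sB_", xb, train)
    skips <- mapply(concat_ch, sA$skips, sB$skips, SIMPLIFY = FALSE)
    bot_in <- concat_ch(sA$out, sB$out)
    cache$sA <- sA$cache; cache$sB <- sB$cache
    cache$poolA_ch <- dim(sA$out)[4]
  } else {
    s <- stream_forward(P, cfg, "", x, train)
    skips <- s$skips
    bot_in <- s$out
    cache$s <- s$cache
  }
  a1 <- relu(conv3d_fw(bot_in, P$bot_conv1_w, P$bot_conv1_b, cfg$kernel))
  a2 <- relu(conv3d_fw(a1, P$bot_conv2_w, P$bot_conv2_b, cfg$kernel))
  dm <- NULL
  if (train && cfg$dropout_rate > 0) {
    dm <- drop_mask(dim(a2)[4], cfg$dropout_rate)
    a2 <- apply_channel_scale(a2, dm)
  }
  cache$bot <- list(x_in = bot_in, a1 = a1, a2 = a2, dm = dm)
  cur <- a2
  cache$dec <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    if (cfg$upsample == "transposed") {
      up <- upconv3d_fw(cur, P[[paste0("dec", l, "_up_w")]],
                        P[[paste0("dec", l, "_up_b")]])
      up_cache <- list(up_in = cur)
    } else {
      cb <- dim(cur)[4]
      upsampled <- upconv3d_fw(cur, identity_up_w(cb), numeric(cb))
      up <- relu(conv3d_fw(upsampled, P[[paste0("dec", l, "_proj_w")]],
                           P[[paste0("dec", l, "_proj_b")]], cfg$kernel))
      up_cache <- list(up_in = cur, upsampled = upsampled, proj_a = up)
    }
    cat_in <- concat_ch(skips[[l]], up)
    a1d <- relu(conv3d_fw(cat_in, P[[paste0("dec", l, "_conv1_w")]],
                          P[[paste0("dec", l, "_conv1_b")]], cfg$kernel))
    a2d <- relu(conv3d_fw(a1d, P[[paste0("dec", l, "_conv2_w")]],
                          P[[paste0("dec", l, "_conv2_b")]], cfg$kernel))
    cache$dec[[l]] <- c(up_cache, list(cat_in = cat_in, a1 = a1d, a2 = a2d,
                                       skip_ch = dim(skips[[l]])[4]))
    cur <- a2d
  }
  z <- conv3d_fw(cur, P$head_w, P$head_b, 1L)
  y <- sigmoid(z)
  cache$head_in <- cur
  cache$y <- y
  if (train) list(y = array(y, dim = dim(y)[1:3]), cache = cache)
  else array(y, dim = dim(y)[1:3])
}

#' Backward pass (gradients of a scalar loss)
#'
#' @param model a `unet3d`.
#' @param cache activation cache from `unet_forward(..., train = TRUE)`.
#' @param dy gradient of the loss with respect to the sigmoid output.
#' @return Named list of gradients matching `model$params`.
#' @export
unet_backward <- function(model, cache, dy) {
  cfg <- model$cfg; P <- model$params
  grads <- list()
  y <- cache$y
  dz <- array(as.numeric(dy) * y * (1 - y), dim = dim(y))
  hb <- conv3d_bw(cache$head_in, P$head_w, dz, 1L)
  grads$head_w <- hb$dw; grads$head_b <- hb$db
  d_a2 <- hb$dx
  d_below <- NULL
  d_skips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    cc <- cache$dec[[l]]
    dz2 <- d_a2 * (cc$a2 > 0)
    bw2 <- conv3d_bw(cc$a1, P[[paste0("dec", l, "_conv2_w")]], dz2, cfg$kernel)
    grads[[paste0("dec", l, "_conv2_w")]] <- bw2$dw
    grads[[paste0("dec", l, "_conv2_b")]] <- bw2$db
    dz1 <- bw2$dx * (cc$a1 > 0)
    bw1 <- conv3d_bw(cc$cat_in, P[[paste0("dec", l, "_conv1_w")]], dz1, cfg$kernel)
    grads[[paste0("dec", l, "_conv1_w")]] <- bw1$dw
    grads[[paste0("dec", l, "_conv1_b")]] <- bw1$db
    sc <- cc$skip_ch
    d3 <- dim(bw1$dx)[1:3]
    ctot <- dim(bw1$dx)[4]
    d_skips[[l]] <- array(bw1$dx[, , , seq_len(sc)], dim = c(d3, sc))
    d_up <- array(bw1$dx[, , , (sc + 1L):ctot], dim = c(d3, ctot - sc))
    if (cfg$upsample == "transposed") {
      ub <- upconv3d_bw(cc$up_in, P[[paste0("dec", l, "_up_w")]], d_up)
      grads[[paste0("dec", l, "_up_w")]] <- ub$dw
      grads[[paste0("dec", l, "_up_b")]] <- ub$db
      d_a2 <- ub$dx
    } else {
      dzp <- d_up * (cc$proj_a > 0)
      pb <- conv3d_bw(cc$upsampled, P[[paste0("dec", l, "_proj_w")]], dzp, cfg$kernel)
      grads[[paste0("dec", l, "_proj_w")]] <- pb$dw
      grads[[paste0("dec", l, "_proj_b")]] <- pb$db
      cb <- dim(cc$up_in)[4]
      ub <- upconv3d_bw(cc$up_in, identity_up_w(cb), pb$dx)
      d_a2 <- ub$dx
    }
  }
  # d_a2 now holds grad at bottleneck output
  bc <- cache$bot
  if (!is.null(bc$dm)) d_a2 <- apply_channel_scale(d_a2, bc$dm)
  dz2 <- d_a2 * (bc$a2 > 0)
  bw2 <- conv3d_bw(bc$a1, P$bot_conv2_w, dz2, cfg$kernel)
  grads$bot_conv2_w <- bw2$dw; grads$bot_conv2_b <- bw2$db
  dz1 <- bw2$dx * (bc$a1 > 0)
  bw1 <- conv3d_bw(bc$x_in, P$bot_conv1_w, dz1, cfg$kernel)
  grads$bot_conv1_w <- bw1$dw; grads$bot_conv1_b <- bw1$db
  if (model$dual) {
    ca <- cache$poolA_ch
    d3 <- dim(bw1$dx)[1:3]
    dA <- array(bw1$dx[, , , seq_len(ca)], dim = c(d3, ca))
    dB <- array(bw1$dx[, , , (ca + 1L):dim(bw1$dx)[4]], dim = c(d3, dim(bw1$dx)[4] - ca))
    splitsk <- function(which) lapply(seq_len(cfg$depth), function(l) {
      ds <- d_skips[[l]]
      half <- dim(ds)[4] %/% 2L
      d3s <- dim(ds)[1:3]
      if (which == 1L) array(ds[, , , seq_len(half)], dim = c(d3s, half))
      else array(ds[, , , (half + 1L):dim(ds)[4]], dim = c(d3s, half))
    })
    grads <- stream_backward(P, cfg, "sA_", cache$sA, dA, splitsk(1L), grads)
    grads <- stream_backward(P, cfg, "sB_", cache$sB, dB, splitsk(2L), grads)
  } else {
    grads <- stream_backward(P, cfg, "", cache$s, bw1$dx, d_skips, grads)
  }
  grads
}

encoder_layer_names <- function(depth, prefix = "") {
  unlist(lapply(seq_len(depth), function(l)
    paste0(prefix, "enc", l, "_", c("conv1_w", "conv1_b", "conv2_w", "conv2_b"))))
}

#' Transfer encoder weights between models
#'
#' Copies the encoder parameters of `src` into `dst` at the selected levels;
#' all other parameters keep their current (fresh) values. Nothing is
#' frozen: transferred weights keep training.
#'
#' @param src source model / weights bundle (single-stream).
#' @param dst destination `unet3d` (single-stream).
#' @param levels integer vector of encoder levels to transfer; default all.
#' @return `dst` with transferred weights.
#' @export
transfer_encoder <- function(src, dst, levels = NULL) {
  if (dst$dual) stop("use concat_dual_encoder() for the dual model")
  if (is.null(levels)) levels <- seq_len(dst$cfg$depth)
  if (length(levels) == 0L) return(dst)
  if (max(levels) > src$cfg$depth) stop("source model has only ", src$cfg$depth, " levels")
  for (nm in encoder_layer_names(dst$cfg$depth)[rep(seq_len(dst$cfg$depth) %in% levels,
                                                    each = 4L)]) {
    if (!identical(dim(src$params[[nm]]), dim(dst$params[[nm]])) ||
        !identical(length(src$params[[nm]]), length(dst$params[[nm]])))
      stop("shape mismatch transferring layer ", nm)
    dst$params[[nm]] <- src$params[[nm]]
  }
  dst
}

#' Build the dual-encoder two-channel model
#'
#' Constructs the two-channel pulmonary-artery model: stream A consumes the
#' non-contrast channel and is initialized from the segmentation pre-train's
#' encoder, stream B consumes the synthesized contrast channel and is
#' initialized from the enhancement model's encoder. At every downsampling
#' level the streams' feature maps are channel-concatenated into the skip
#' connections of a shared decoder, which (with the bottleneck and head) is
#' initialized from the pre-train wherever shapes permit and freshly
#' elsewhere.
#'
#' @param seg_pretrain single-stream segmentation model (weights bundle).
#' @param enhancement enhancement-stage model (weights bundle).
#' @param cfg optional [net_config()]; defaults to the pre-train's config
#'   with `in_channels = 2`.
#' @return A dual `unet3d` with stage `"segmentation_pretrain"` encoders.
#' @export
concat_dual_encoder <- function(seg_pretrain, enhancement, cfg = NULL) {
  if (seg_pretrain$cfg$depth != enhancement$cfg$depth ||
      seg_pretrain$cfg$base_filters != enhancement$cfg$base_filters)
    stop("depth/base_filters mismatch between the two source bundles")
  if (is.null(cfg)) {
    cfg <- seg_pretrain$cfg
    cfg$in_channels <- 2L
  }
  model <- build_unet3d(cfg, dual = TRUE)
  for (l in seq_len(cfg$depth)) {
    for (part in c("conv1_w", "conv1_b", "conv2_w", "conv2_b")) {
      nm <- paste0("enc", l, "_", part)
      model$params[[paste0("sA_", nm)]] <- seg_pretrain$params[[nm]]
      model$params[[paste0("sB_", nm)]] <- enhancement$params[[nm]]
    }
  }
  # decoder / bottleneck / head: reuse pre-train weights where shapes agree
  for (nm in names(model$params)) {
    if (startsWith(nm, "sA_") || startsWith(nm, "sB_")) next
    src <- seg_pretrain$params[[nm]]
    if (!is.null(src) && identical(dim(src), dim(model$params[[nm]])) &&
        identical(length(src), length(model$params[[nm]])))
      model$params[[nm]] <- src
  }
  model$stage <- "segmentation_pretrain"
  model
}

#' Save / load model checkpoints
#'
#' Checkpoints store the full weights bundle: parameters, configuration and
#' stage tag. The round trip is bitwise exact.
#'
#' @param model a `unet3d`.
#' @param path checkpoint file path (`.rds`).
#' @return [load_checkpoint()] returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet3d")) stop("not a unet3d checkpoint: ", path)
  model
}
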