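#' Training configuration
#'
#' Defaults follow the full-scale reference schedule (learning rate 1e-2,
#' decay 1e-6, sigmoid output, spatial dropout 0.25 in [net_config()]) with
#' a desk-scale epoch budget. `decay` is interpreted as a per-step
#' multiplicative learning-rate decay, `lr_t = lr / (1 + decay * t)`; set
#' `decay_mode = "weight"` for L2 weight decay instead.
#'
#' @param learning_rate positive step size.
#' @param decay decay constant (see above).
#' @param decay_mode `"lr"` (default) or `"weight"`.
#' @param epochs training epochs.
#' @param batch_size samples per gradient step (gradients are averaged).
#' @param seed integer seed driving initialization, shuffling and dropout.
#' @param loss a [loss_config()].
#' @param threshold probability cutoff for mask binarization.
#' @param patience early-stopping patience (validation evaluations without
#'   improvement); `Inf` disables.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param patch_size optional cubic patch extent (voxels). When set, each
#'   epoch trains on random sub-volumes centred near the structure of
#'   interest (the standard patch strategy for 3D training); validation and
#'   inference always run on full grids.
#' @param patches_per_epoch random patches drawn per sample per epoch (so
#'   one epoch performs `n * patches_per_epoch / batch_size` optimizer
#'   steps).
#' @param val_every evaluate validation loss every this many epochs.
#' @param verbose print per-epoch losses.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-2, decay = 1e-6,
                         decay_mode = c("lr", "weight"), epochs = 50L,
                         batch_size = 2L, seed = 1L, loss = loss_config(),
                         threshold = 0.5, patience = 20L,
                         optimizer = c("adam", "sgd"), patch_size = NULL,
                         patches_per_epoch = 1L, val_every = 1L,
                         verbose = FALSE) {
  decay_mode <- match.arg(decay_mode)
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, decay = decay,
                 decay_mode = decay_mode, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = loss, threshold = threshold, patience = patience,
                 optimizer = optimizer,
                 patch_size = if (is.null(patch_size)) NULL else as.integer(patch_size),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 val_every = as.integer(val_every), verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

optimizer_step <- function(model, grads, state, cfg) {
  state$t <- state$t + 1L
  lr <- cfg$learning_rate
  if (cfg$decay_mode == "lr") lr <- lr / (1 + cfg$decay * state$t)
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (cfg$decay_mode == "weight") g <- g + cfg$decay * model$params[[nm]]
    if (cfg$optimizer == "adam") {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
      mh <- state$m[[nm]] / (1 - b1^state$t)
      vh <- state$v[[nm]] / (1 - b2^state$t)
      model$params[[nm]] <- model$params[[nm]] - lr * mh / (sqrt(vh) + eps)
    } else {
      model$params[[nm]] <- model$params[[nm]] - lr * g
    }
  }
  list(model = model, state = state)
}

accumulate_grads <- function(acc, grads, scale) {
  if (is.null(acc)) return(lapply(grads, function(g) g * scale))
  for (nm in names(grads)) acc[[nm]] <- acc[[nm]] + grads[[nm]] * scale
  acc
}

# Candidate patch centres: voxels where the target is foreground (1 for
# masks; bright, i.e. > 0.7 on the normalized scale, for enhancement
# targets, which puts centres on the contrast-filled vessel); falls back to
# all voxels for featureless targets.
patch_centers <- function(target) {
  thr <- if (all(target %in% c(0, 1))) 0.5 else 0.7
  idx <- which(target > thr)
  if (length(idx) == 0L) idx <- seq_along(target)
  idx
}

crop_patch <- function(s, size, center_lin) {
  d <- dim(s$x)[1:3]
  ctr <- arrayInd(center_lin, d)[1, ]
  start <- pmin(pmax(ctr - size %/% 2L, 1L), d - size + 1L)
  xi <- start[1]:(start[1] + size - 1L)
  yi <- start[2]:(start[2] + size - 1L)
  zi <- start[3]:(start[3] + size - 1L)
  list(x = s$x[xi, yi, zi, , drop = FALSE],
       target = s$target[xi, yi, zi])
}

# Shared mini-batch training loop. `samples` is a list of
# list(x = 4D input array, target = array); `loss_grad_fn(pred, target)`
# returns list(value, grad). Returns model + history; restores the best
# validation checkpoint when validation samples are given.
fit_unet <- function(model, samples, val_samples, cfg, loss_grad_fn, loss_fn,
                     metric_fn = NULL) {
  set.seed(cfg$seed)
  state <- adam_init(model$params)
  n <- length(samples)
  patching <- !is.null(cfg$patch_size) &&
    any(dim(samples[[1]]$x)[1:3] > cfg$patch_size)
  if (patching)
    centers <- lapply(samples, function(s) patch_centers(s$target))
  hist <- list()
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  ppe <- if (!is.null(cfg$patches_per_epoch)) max(1L, cfg$patches_per_epoch) else 1L
  for (ep in seq_len(cfg$epochs)) {
    ord <- rep(sample.int(n), ppe)
    ne <- length(ord)
    tr_loss <- 0
    for (b0 in seq(1, ne, by = cfg$batch_size)) {
      idx <- ord[b0:min(ne, b0 + cfg$batch_size - 1L)]
      acc <- NULL
      for (i in idx) {
        s <- if (patching)
          crop_patch(samples[[i]], cfg$patch_size,
                     sample(centers[[i]], 1L)) else samples[[i]]
        fw <- unet_forward(model, s$x, train = TRUE)
        lg <- loss_grad_fn(fw$y, s$target)
        tr_loss <- tr_loss + lg$value
        grads <- unet_backward(model, fw$cache, lg$grad)
        acc <- accumulate_grads(acc, grads, 1 / length(idx))
      }
      st <- optimizer_step(model, acc, state, cfg)
      model <- st$model; state <- st$state
    }
    tr_loss <- tr_loss / ne
    va_loss <- NA_real_
    va_metric <- NA_real_
    if (length(val_samples) > 0 &&
        (ep %% cfg$val_every == 0L || ep == cfg$epochs)) {
      vl <- vapply(val_samples, function(s)
        loss_fn(unet_forward(model, s$x), s$target), numeric(1))
      va_loss <- mean(vl)
      if (!is.null(metric_fn))
        va_metric <- mean(vapply(val_samples, function(s)
          metric_fn(unet_forward(model, s$x), s$target), numeric(1)))
      if (va_loss < best$loss - 1e-9) {
        best <- list(loss = va_loss, params = model$params, epoch = ep)
        wait <- 0L
      } else wait <- wait + 1L
    }
    hist[[ep]] <- data.frame(epoch = ep, train_loss = tr_loss,
                             val_loss = va_loss, val_metric = va_metric)
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  dsc %.4f",
                      ep, tr_loss, va_loss, va_metric))
    if (length(val_samples) > 0 && wait >= cfg$patience) break
  }
  if (length(val_samples) > 0 && best$epoch > 0L) model$params <- best$params
  attr(model, "history") <- do.call(rbind, hist)
  model
}

check_pairs <- function(pairs) {
  for (p in pairs) {
    if (!all(c("nc", "ce") %in% names(p))) stop("each pair needs elements nc and ce")
    if (!identical(dim(as_4d(p$nc)), dim(as_4d(p$ce))))
      stop("nc/ce grids differ within a pair")
  }
}

#' Train the stage-1 contrast-enhancement model
#'
#' Learns a voxelwise mapping from the normalized non-contrast volume to its
#' contrast-enhanced counterpart by minimizing the composite
#' `alpha * MAE + (1 - alpha) * DSSIM` loss. When validation pairs are given,
#' the best-validation-loss parameters are restored at the end, so the
#' checkpointed validation loss is non-increasing over training.
#'
#' @param pairs list of `list(nc = , ce = )` normalized `ct_volume`s (or
#'   arrays) on identical grids.
#' @param cfg a [train_config()].
#' @param net a [net_config()]; default depth-3, 8 base filters.
#' @param val_pairs optional held-out pairs for checkpoint selection.
#' @return The trained model (stage `"enhancement"`) with a per-epoch
#'   `history` attribute.
#' @export
train_enhancement <- function(pairs, cfg = train_config(),
                              net = net_config(in_channels = 1L),
                              val_pairs = list()) {
  check_pairs(pairs)
  check_pairs(val_pairs)
  lcfg <- cfg$loss
  mk <- function(p) list(x = as_4d(p$nc), target = as_grid_3d(p$ce))
  samples <- lapply(pairs, mk)
  vals <- lapply(val_pairs, mk)
  set.seed(cfg$seed)
  model <- build_unet3d(net)
  model <- fit_unet(model, samples, vals, cfg,
                    loss_grad_fn = function(pred, target)
                      combined_loss_grad(pred, target, lcfg),
                    loss_fn = function(pred, target)
                      combined_loss(pred, target, lcfg))
  model$stage <- "enhancement"
  model
}

as_grid_3d <- function(x) {
  x <- if (inherits(x, "ct_volume")) x$data else x
  if (length(dim(x)) == 4L && dim(x)[4] == 1L) dim(x) <- dim(x)[1:3]
  x
}

#' Synthesize a contrast-enhanced volume
#'
#' Runs the stage-1 model on a normalized non-contrast volume. Output values
#' lie in (0, 1) (sigmoid head).
#'
#' @param nc normalized `ct_volume` (or array).
#' @param model enhancement-stage model.
#' @return A normalized `ct_volume` on the same grid.
#' @export
enhance <- function(nc, model) {
  if (!identical(model$stage, "enhancement"))
    stop("model stage is '", model$stage, "', expected 'enhancement'")
  y <- unet_forward(model, nc)
  if (inherits(nc, "ct_volume"))
    ct_volume(y, spacing = nc$spacing, origin = nc$origin,
              intensity_kind = "normalized")
  else y
}

#' Train a stage-2 segmentation model
#'
#' Minimizes the soft Dice loss `1 - DSC`. Three initialization schemes
#' mirror the two-stage design: `"fresh"` (random), `"encoder_transfer"`
#' (encoder initialized from the enhancement model; single-channel aorta
#' path), and `"dual_concat"` (two-channel dual-encoder model from a
#' segmentation pre-train plus the enhancement model; pulmonary-artery
#' path).
#'
#' @param samples list of `list(x = , mask = )`; `x` is a normalized volume
#'   (single-channel) or an `(X, Y, Z, 2)` array of (non-contrast, enhanced)
#'   channels for the dual scheme.
#' @param cfg a [train_config()].
#' @param init initialization scheme.
#' @param net a [net_config()] (ignored for `"dual_concat"`, which inherits
#'   the pre-train's architecture).
#' @param enhancement enhancement model (for `"encoder_transfer"` and
#'   `"dual_concat"`).
#' @param seg_pretrain single-channel segmentation pre-train (for
#'   `"dual_concat"`).
#' @param val_samples optional held-out samples for checkpoint selection.
#' @return The trained model (stage `"final"`) with a `history` attribute
#'   whose `val_metric` column is the validation DSC.
#' @export
train_segmentation <- function(samples, cfg = train_config(),
                               init = c("fresh", "encoder_transfer", "dual_concat"),
                               net = net_config(in_channels = 1L),
                               enhancement = NULL, seg_pretrain = NULL,
                               val_samples = list()) {
  init <- match.arg(init)
  set.seed(cfg$seed)
  if (init == "dual_concat") {
    if (is.null(seg_pretrain) || is.null(enhancement))
      stop("dual_concat needs both seg_pretrain and enhancement bundles")
    model <- concat_dual_encoder(seg_pretrain, enhancement)
  } else {
    model <- build_unet3d(net)
    if (init == "encoder_transfer") {
      if (is.null(enhancement)) stop("encoder_transfer needs the enhancement bundle")
      model <- transfer_encoder(enhancement, model)
    }
    # start the sigmoid head at the foreground-prior logit: with a
    # zero-initialized head the soft Dice gradient is dominated by the vast
    # background and can drive the network into the empty-prediction
    # attractor before it learns anything
    fg <- mean(vapply(samples, function(s) mean(as_grid_3d(s$mask)), numeric(1)))
    fg <- min(max(fg, 1e-4), 0.5)
    model$params$head_b <- log(fg / (1 - fg))
  }
  want_ch <- model$cfg$in_channels
  mk <- function(s) {
    x <- as_4d(s$x)
    if (dim(x)[4] != want_ch)
      stop("sample has ", dim(x)[4], " channel(s) but init scheme '", init,
           "' expects ", want_ch)
    list(x = x, target = as_grid_3d(s$mask))
  }
  tr <- lapply(samples, mk)
  va <- lapply(val_samples, mk)
  smooth <- cfg$loss$dice_smooth
  thr <- cfg$threshold
  model <- fit_unet(model, tr, va, cfg,
                    loss_grad_fn = function(pred, target)
                      dice_loss_grad(pred, target, smooth),
                    loss_fn = function(pred, target)
                      dice_loss(pred, target, smooth),
                    metric_fn = function(pred, target)
                      dsc_binary((pred >= thr) * 1, target))
  model$stage <- "final"
  model
}

#' Predict a binary mask
#'
#' Thresholds the sigmoid output and optionally keeps only the largest
#' 26-connected component.
#'
#' @param x input volume/array (channels as required by the model).
#' @param model trained segmentation model.
#' @param threshold cutoff in (0, 1).
#' @param largest_component keep only the largest connected component.
#' @return A mask `ct_volume` if `x` carries geometry, else a binary array.
#' @export
predict_mask <- function(x, model, threshold = 0.5, largest_component = TRUE) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be inside (0, 1)")
  y <- unet_forward(model, x)
  m <- (y >= threshold) * 1
  if (largest_component) m <- keep_largest_component(m)
  dim(m) <- dim(y)
  if (inherits(x, "ct_volume"))
    ct_volume(m, spacing = x$spacing, origin = x$origin, intensity_kind = "mask")
  else m
}

#' Keep only the largest 26-connected component of a binary array
#'
#' @param m binary 3D array.
#' @return Binary array of the same shape.
#' @export
keep_largest_component <- function(m) {
  if (!any(m > 0)) return(m)
  d <- dim(m)
  lab <- label3d(m, 26L)
  sizes <- tabulate(lab)
  out <- (lab == which.max(sizes)) * 1
  dim(out) <- d
  out
}

#' Deterministic k-fold plan
#'
#' Partitions `n` samples into `k` folds whose sizes differ by at most one;
#' the assignment is a deterministic function of `seed`.
#'
#' @param n number of samples.
#' @param k fold count.
#' @param seed integer seed.
#' @return Integer vector of fold indices (1..k) per sample.
#' @export
fold_plan <- function(n, k = 5L, seed = 1L) {
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Summarize per-fold scores
#' @param dscs numeric vector of per-fold DSC values.
#' @return list(mean, sd, per_fold).
#' @export
cv_summary <- function(dscs) {
  list(mean = mean(dscs), sd = stats::sd(dscs), per_fold = dscs)
}

#' k-fold cross-validated segmentation evaluation
#'
#' Re-trains the stage-2 model on each training fold and evaluates the
#' binary DSC on the held-out fold; the stage-1 enhancement bundle (if used
#' by the init scheme) is trained once beforehand and shared across folds.
#'
#' @param samples list of `list(x = , mask = )` segmentation samples.
#' @param k fold count (default 5).
#' @param cfg a [train_config()].
#' @param ... passed to [train_segmentation()] (init scheme, bundles, net).
#' @return list(mean, sd, per_fold, assignment).
#' @export
crossvalidate <- function(samples, k = 5L, cfg = train_config(), ...) {
  n <- length(samples)
  assignment <- fold_plan(n, k, cfg$seed)
  per_fold <- numeric(k)
  for (fold in seq_len(k)) {
    tr <- samples[assignment != fold]
    te <- samples[assignment == fold]
    model <- train_segmentation(tr, cfg, ...)
    dscs <- vapply(te, function(s) {
      pm <- predict_mask(s$x, model, cfg$threshold)
      dsc_binary(as_grid_3d(pm), as_grid_3d(s$mask))
    }, numeric(1))
    per_fold[fold] <- mean(dscs)
  }
  out <- cv_summary(per_fold)
  out$assignment <- assignment
  out
}
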