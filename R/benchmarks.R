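norm_nc <- function(p) window_normalize(p$nc)

seg_sample_1ch <- function(p) {
  v <- norm_nc(p)
  list(x = array(v$data, dim = c(dim(v$data), 1L)), mask = p$mask$data)
}

seg_sample_2ch <- function(p, enh_model) {
  v <- norm_nc(p)
  e <- enhance(v, enh_model)
  list(x = array(c(v$data, e$data), dim = c(dim(v$data), 2L)),
       mask = p$mask$data)
}

#' Desk-scale benchmark of the two-stage segmentation pipeline
#'
#' Runs the full two-stage pipeline on synthetic phantoms at desk scale:
#' generates paired non-contrast/contrast phantoms, trains the stage-1
#' contrast-enhancement network (composite MAE+DSSIM loss) on a disjoint
#' enhancement split, then trains the stage-2 segmentation network — the
#' single-channel encoder-transferred model on arch phantoms for the aorta
#' task, or the dual-encoder two-channel model (segmentation pre-train +
#' enhancement encoders) on bifurcating-tree phantoms for the
#' pulmonary-artery task — and reports the held-out Dice similarity
#' coefficient.
#'
#' Desk-scale training choices (tiny depth-3 network, 32-voxel patches with
#' several random patches per volume per epoch, Adam at 3e-3, no dropout)
#' are fixed defaults chosen for single-CPU runtimes of a few minutes; the
#' phantom intensity/noise conditions are the package defaults of
#' [phantom_spec()].
#'
#' @param task `"aorta"` (torus-arch phantoms, single-channel model) or
#'   `"pa"` (bifurcating-tree phantoms, two-channel model).
#' @param seed integer seed driving phantom generation and all training;
#'   defaults to 7 for the aorta task and 11 for the PA task.
#' @param n_phantoms segmentation-split phantoms (train + val + test).
#' @param n_enhance phantoms in the disjoint enhancement split.
#' @param n_val,n_test validation / held-out test phantom counts.
#' @param grid_shape phantom grid (voxels).
#' @param radius_range_mm jitter range of the (trunk) tube radius; defaults
#'   3-6 mm (aorta) or 3-5 mm (PA).
#' @param depth,base_filters network size.
#' @param patch_size,learning_rate,epochs_enhance,epochs_pretrain,epochs_seg
#'   training schedule.
#' @param threshold binarization cutoff for evaluation.
#' @param keep_test also return the held-out phantoms with their predicted
#'   masks (used by [run_pipeline()] for downstream diametry).
#' @param verbose print per-epoch losses.
#' @return A list: `task`, `mean_dsc`, `dsc` (per held-out phantom),
#'   `contrast_nc` / `contrast_enhanced` (vessel-background contrast before
#'   and after stage-1 on the first test phantom), the trained `models`,
#'   and `elapsed_min`.
#' @export
scaled_vessel_benchmark <- function(task = c("aorta", "pa"), seed = NULL,
                                    n_phantoms = 16, n_enhance = 8,
                                    n_val = 2, n_test = 4,
                                    grid_shape = c(64, 64, 64),
                                    radius_range_mm = NULL,
                                    depth = 3, base_filters = 4,
                                    patch_size = 32, learning_rate = 3e-3,
                                    epochs_enhance = 30, epochs_pretrain = 15,
                                    epochs_seg = 30, threshold = 0.5,
                                    keep_test = FALSE, verbose = FALSE) {
  task <- match.arg(task)
  t0 <- Sys.time()
  if (is.null(seed)) seed <- if (task == "aorta") 7L else 11L
  seed <- as.integer(seed)
  geometry <- if (task == "aorta") "torus_arch" else "bifurcating_tree"
  if (is.null(radius_range_mm))
    radius_range_mm <- if (task == "aorta") c(3, 6) else c(3, 5)
  base <- phantom_spec(geometry, grid_shape = grid_shape, seed = seed)
  jit <- list(tube_radius_mm = radius_range_mm)
  phs <- generate_phantoms(n_phantoms, base, jitter = jit, seed = seed)
  phs_enh <- generate_phantoms(n_enhance, base, jitter = jit, seed = seed + 1L)
  net <- net_config(in_channels = 1L, depth = depth,
                    base_filters = base_filters, dropout_rate = 0)
  mkcfg <- function(epochs, seed_off, ppe, val_every = 100L)
    train_config(learning_rate = learning_rate, epochs = epochs,
                 seed = seed + seed_off, batch_size = 1L,
                 patch_size = patch_size, patches_per_epoch = ppe,
                 val_every = val_every, threshold = threshold,
                 verbose = verbose)
  pairs <- lapply(phs_enh, function(p) list(nc = norm_nc(p),
                                            ce = window_normalize(p$ce)))
  enh <- train_enhancement(pairs, mkcfg(epochs_enhance, 101L, 4L), net)
  n_train <- n_phantoms - n_val - n_test
  idx_tr <- seq_len(n_train)
  idx_va <- n_train + seq_len(n_val)
  idx_te <- n_train + n_val + seq_len(n_test)
  if (task == "aorta") {
    ss <- lapply(phs, seg_sample_1ch)
    seg <- train_segmentation(ss[idx_tr], mkcfg(epochs_seg, 102L, 3L, 5L),
                              init = "encoder_transfer", net = net,
                              enhancement = enh, val_samples = ss[idx_va])
    models <- list(enhancement = enh, segmentation = seg)
  } else {
    s1 <- lapply(phs, seg_sample_1ch)
    pre <- train_segmentation(s1[idx_tr], mkcfg(epochs_pretrain, 102L, 3L),
                              init = "fresh", net = net)
    ss <- lapply(phs, seg_sample_2ch, enh_model = enh)
    seg <- train_segmentation(ss[idx_tr], mkcfg(epochs_seg, 103L, 3L, 5L),
                              init = "dual_concat", enhancement = enh,
                              seg_pretrain = pre, val_samples = ss[idx_va])
    models <- list(enhancement = enh, seg_pretrain = pre, segmentation = seg)
  }
  preds <- lapply(ss[idx_te], function(s) predict_mask(s$x, seg, threshold))
  dscs <- mapply(function(pm, s) dsc_binary(pm, s$mask), preds, ss[idx_te])
  test <- NULL
  if (keep_test)
    test <- lapply(seq_along(idx_te), function(i) {
      ph <- phs[[idx_te[i]]]
      list(phantom = ph,
           mask_pred = ct_volume(preds[[i]], spacing = ph$mask$spacing,
                                 origin = ph$mask$origin,
                                 intensity_kind = "mask"),
           dsc = dscs[i])
    })
  p1 <- phs[[idx_te[1]]]
  m <- p1$mask$data > 0
  vnc <- norm_nc(p1)$data
  ven <- enhance(norm_nc(p1), enh)$data
  list(task = task, seed = seed,
       mean_dsc = mean(dscs), dsc = dscs,
       contrast_nc = mean(vnc[m]) - mean(vnc[!m]),
       contrast_enhanced = mean(ven[m]) - mean(ven[!m]),
       models = models, test = test,
       elapsed_min = as.numeric(Sys.time() - t0, units = "mins"))
}

#' Two-channel versus single-channel ablation
#'
#' Repeats, under seeded conditions, the comparison between the dual-encoder
#' two-channel pulmonary-artery model (non-contrast + synthesized contrast
#' channels) and the single-channel non-contrast-only model, at matched
#' final-stage training budgets on low-contrast bifurcating-tree phantoms.
#' The expected effect is an ordering (two-channel at least as good on
#' average), not a fixed margin.
#'
#' @param repeats number of seeded repetitions.
#' @param seed base seed; repeat r uses `seed + 101 * r`.
#' @param n_phantoms phantoms per repeat (last two held out).
#' @param grid_shape phantom grid; default 32^3 keeps a repeat under a
#'   minute.
#' @param depth,base_filters,patch_size,learning_rate network/schedule.
#' @param epochs_enhance,epochs_pretrain,epochs_seg schedule (the final
#'   models share `epochs_seg`).
#' @return A list with `table` (per-repeat DSC of both models),
#'   `mean_dual`, `mean_single`, and `benefit` (their difference).
#' @export
channel_ablation_benchmark <- function(repeats = 5, seed = 1L, n_phantoms = 8,
                                       grid_shape = c(32, 32, 32),
                                       depth = 2, base_filters = 4,
                                       patch_size = 32, learning_rate = 3e-3,
                                       epochs_enhance = 10, epochs_pretrain = 6,
                                       epochs_seg = 12) {
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    sr <- as.integer(seed + 101L * r)
    base <- phantom_spec("bifurcating_tree", grid_shape = grid_shape, seed = sr)
    jit <- list(tube_radius_mm = c(3, 5))
    phs <- generate_phantoms(n_phantoms, base, jitter = jit, seed = sr)
    phs_enh <- generate_phantoms(4, base, jitter = jit, seed = sr + 1L)
    net <- net_config(in_channels = 1L, depth = depth,
                      base_filters = base_filters, dropout_rate = 0)
    mkcfg <- function(epochs, off, ppe)
      train_config(learning_rate = learning_rate, epochs = epochs,
                   seed = sr + off, batch_size = 1L, patch_size = patch_size,
                   patches_per_epoch = ppe, val_every = 100L)
    pairs <- lapply(phs_enh, function(p) list(nc = norm_nc(p),
                                              ce = window_normalize(p$ce)))
    enh <- train_enhancement(pairs, mkcfg(epochs_enhance, 11L, 4L), net)
    idx_tr <- seq_len(n_phantoms - 2L)
    idx_te <- n_phantoms - c(1L, 0L)
    s1 <- lapply(phs, seg_sample_1ch)
    s2 <- lapply(phs, seg_sample_2ch, enh_model = enh)
    pre <- train_segmentation(s1[idx_tr], mkcfg(epochs_pretrain, 12L, 2L),
                              init = "fresh", net = net)
    dual <- train_segmentation(s2[idx_tr], mkcfg(epochs_seg, 13L, 2L),
                               init = "dual_concat", enhancement = enh,
                               seg_pretrain = pre)
    single <- train_segmentation(s1[idx_tr], mkcfg(epochs_seg, 13L, 2L),
                                 init = "fresh", net = net)
    d_dual <- mean(vapply(s2[idx_te], function(s)
      dsc_binary(predict_mask(s$x, dual), s$mask), numeric(1)))
    d_single <- mean(vapply(s1[idx_te], function(s)
      dsc_binary(predict_mask(s$x, single), s$mask), numeric(1)))
    rows[[r]] <- data.frame(repeat_id = r, seed = sr,
                            dsc_dual = d_dual, dsc_single = d_single)
  }
  tab <- do.call(rbind, rows)
  list(table = tab, mean_dual = mean(tab$dsc_dual),
       mean_single = mean(tab$dsc_single),
       benefit = mean(tab$dsc_dual) - mean(tab$dsc_single))
}
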