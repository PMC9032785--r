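#' Loss configuration
#'
#' Bundles the tunable constants of the composite enhancement loss and the
#' Dice loss. The enhancement loss is
#' `alpha * MAE + (1 - alpha) * DSSIM`, with `alpha = 0.7` as the default
#' trade-off; DSSIM is `(1 - SSIM) / 2` so both terms live on \[0, 1\] for
#' normalized images.
#'
#' @param alpha trade-off between MAE and DSSIM, in \[0, 1\].
#' @param ssim_window odd cubic window extent for the local SSIM statistics.
#' @param ssim_k1,ssim_k2 SSIM stabilizer constants (literature defaults).
#' @param data_range dynamic range of the images (1 for normalized volumes).
#' @param dice_smooth additive smoothing used in the Dice loss during
#'   training (avoids 0/0 on empty predictions); set 0 for evaluation.
#' @return A `loss_config` object.
#' @export
loss_config <- function(alpha = 0.7, ssim_window = 7, ssim_k1 = 0.01,
                        ssim_k2 = 0.03, data_range = 1, dice_smooth = 1e-6) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (ssim_window < 3 || ssim_window %% 2 == 0) stop("ssim_window must be odd and >= 3")
  if (data_range <= 0) stop("data_range must be positive")
  structure(list(alpha = alpha, ssim_window = as.integer(ssim_window),
                 ssim_k1 = ssim_k1, ssim_k2 = ssim_k2,
                 data_range = data_range, dice_smooth = dice_smooth),
            class = "loss_config")
}

as_grid <- function(x) {
  if (inherits(x, "ct_volume")) x$data else x
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: (", paste(dim(a), collapse = ","), ") vs (",
         paste(dim(b), collapse = ","), ")")
}

#' Mean absolute error
#'
#' @param pred,target numeric grids (or `ct_volume`s) of identical shape.
#' @param reduce `"mean"` (default) or `"sum"` over voxels.
#' @return A nonnegative scalar.
#' @export
mae <- function(pred, target, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  pred <- as_grid(pred); target <- as_grid(target)
  check_same_shape(pred, target)
  s <- sum(abs(pred - target))
  if (reduce == "mean") s / length(pred) else s
}

# SSIM statistics maps on the valid (full-window) region. Returns the per-
# centre maps needed by both the value and its gradient.
ssim_stats <- function(a, b, cfg) {
  d <- dim(a)
  w <- cfg$ssim_window
  if (any(d < w)) stop("ssim window (", w, ") larger than grid (",
                       paste(d, collapse = ","), ")")
  r <- (w - 1L) %/% 2L
  n <- w^3
  crop <- function(x) x[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r),
                        drop = FALSE]
  mua <- crop(boxsum3d(a, w)) / n
  mub <- crop(boxsum3d(b, w)) / n
  m2a <- crop(boxsum3d(a * a, w)) / n
  m2b <- crop(boxsum3d(b * b, w)) / n
  mab <- crop(boxsum3d(a * b, w)) / n
  C1 <- (cfg$ssim_k1 * cfg$data_range)^2
  C2 <- (cfg$ssim_k2 * cfg$data_range)^2
  va <- m2a - mua^2
  vb <- m2b - mub^2
  cab <- mab - mua * mub
  A1 <- 2 * mua * mub + C1
  A2 <- 2 * cab + C2
  B1 <- mua^2 + mub^2 + C1
  B2 <- va + vb + C2
  list(S = A1 * A2 / (B1 * B2), mua = mua, mub = mub, A1 = A1, A2 = A2,
       B1 = B1, B2 = B2, r = r, n = n, d = d, w = w)
}

#' Structural similarity of two 3D grids
#'
#' Mean local SSIM over a sliding cubic window (uniform weighting), using the
#' standard luminance/contrast/structure formulation with stabilizers
#' `C1 = (k1 * data_range)^2`, `C2 = (k2 * data_range)^2`. Only fully
#' supported (interior) window positions contribute.
#'
#' @param a,b numeric grids (or `ct_volume`s) of identical shape.
#' @param cfg a [loss_config()].
#' @return A scalar in \[-1, 1\].
#' @export
ssim3d <- function(a, b, cfg = loss_config()) {
  a <- as_grid(a); b <- as_grid(b)
  check_same_shape(a, b)
  mean(ssim_stats(a, b, cfg)$S)
}

# Value and analytic gradient of mean SSIM with respect to `a`.
# Derivation: with box means mu_a = B(a)/n, m2 = B(a^2)/n, m3 = B(ab)/n and
# S = A1*A2/(B1*B2), the chain rule through the three filtered maps gives
# dL/da = (B*(G1) + 2a.B*(G2) + b.B*(G3)) / (n*M), where B* is the adjoint
# box sum and G1, G2, G3 are the per-centre partials w.r.t. mu_a, m2, m3.
ssim3d_grad <- function(a, b, cfg = loss_config()) {
  st <- ssim_stats(a, b, cfg)
  M <- length(st$S)
  S <- st$S
  B1 <- st$B1; B2 <- st$B2; A1 <- st$A1; A2 <- st$A2
  mua <- st$mua; mub <- st$mub
  G1 <- (2 * mub * A2 - 2 * mub * A1) / (B1 * B2) -
    S * (2 * mua / B1 - 2 * mua / B2)
  G2 <- -S / B2
  G3 <- 2 * A1 / (B1 * B2)
  d <- st$d; r <- st$r
  embed <- function(g) {
    full <- array(0, dim = d)
    full[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r)] <- g
    full
  }
  grad <- (boxsum3d(embed(G1), st$w) +
             2 * a * boxsum3d(embed(G2), st$w) +
             b * boxsum3d(embed(G3), st$w)) / (st$n * M)
  list(value = mean(S), grad = grad)
}

#' Structural dissimilarity
#'
#' `DSSIM = (1 - SSIM) / 2`, mapping identical images to 0 and perfectly
#' anti-correlated structure to 1.
#'
#' @inheritParams ssim3d
#' @return A scalar in \[0, 1\].
#' @export
dssim <- function(a, b, cfg = loss_config()) {
  (1 - ssim3d(a, b, cfg)) / 2
}

#' Composite contrast-enhancement loss
#'
#' `alpha * MAE(pred, target) + (1 - alpha) * DSSIM(pred, target)`: the MAE
#' term drives overall intensity fidelity, the DSSIM term structural
#' fidelity; `alpha = 0.7` by default.
#'
#' @inheritParams mae
#' @param cfg a [loss_config()].
#' @return A nonnegative scalar.
#' @export
combined_loss <- function(pred, target, cfg = loss_config()) {
  pred <- as_grid(pred); target <- as_grid(target)
  check_same_shape(pred, target)
  m <- mae(pred, target)
  d <- if (cfg$alpha < 1) dssim(pred, target, cfg) else 0
  cfg$alpha * m + (1 - cfg$alpha) * d
}

# Value and gradient of the composite loss w.r.t. pred (used in training).
combined_loss_grad <- function(pred, target, cfg = loss_config()) {
  m <- mae(pred, target)
  dmae <- sign(pred - target) / length(pred)
  if (cfg$alpha < 1) {
    sg <- ssim3d_grad(pred, target, cfg)
    dval <- (1 - sg$value) / 2
    grad <- cfg$alpha * dmae + (1 - cfg$alpha) * (-0.5) * sg$grad
    value <- cfg$alpha * m + (1 - cfg$alpha) * dval
  } else {
    grad <- dmae
    value <- m
  }
  list(value = value, grad = grad)
}

#' Soft Dice coefficient and Dice loss
#'
#' `dice_coefficient` implements the squared-denominator soft Dice
#' `(2 * sum(p g) + s) / (sum(p^2) + sum(g^2) + s)`; on binary inputs with
#' `smooth = 0` it coincides with the set-cardinality form [dsc_binary()].
#' The training loss is `1 - dice_coefficient`.
#'
#' @param pred,target grids with values in \[0, 1\], identical shape.
#' @param smooth nonnegative additive smoothing.
#' @return A scalar in \[0, 1\].
#' @export
dice_coefficient <- function(pred, target, smooth = 0) {
  pred <- as_grid(pred); target <- as_grid(target)
  check_same_shape(pred, target)
  (2 * sum(pred * target) + smooth) / (sum(pred^2) + sum(target^2) + smooth)
}

#' @rdname dice_coefficient
#' @export
dice_loss <- function(pred, target, smooth = 1e-6) {
  1 - dice_coefficient(pred, target, smooth)
}

# Value and gradient of the Dice loss w.r.t. pred.
dice_loss_grad <- function(pred, target, smooth = 1e-6) {
  s1 <- sum(pred * target)
  s2 <- sum(pred^2) + sum(target^2)
  num <- 2 * s1 + smooth
  den <- s2 + smooth
  dsc <- num / den
  # d(1 - num/den)/dp = -(2*g*den - num*2*p) / den^2
  grad <- -(2 * target * den - num * 2 * pred) / den^2
  list(value = 1 - dsc, grad = grad)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary grids (or mask `ct_volume`s) of identical shape.
#' @return A scalar in \[0, 1\].
#' @export
dsc_binary <- function(a, b) {
  a <- as_grid(a); b <- as_grid(b)
  check_same_shape(a, b)
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("dsc_binary expects binary (0/1) masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a * b) / (na + nb)
}
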