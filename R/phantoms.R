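#' Specify a synthetic vessel phantom
#'
#' Phantoms emulate paired non-contrast / contrast-enhanced renderings of
#' tubular vessel geometry on a regular CT grid: a `straight_tube` (cylinder),
#' a `torus_arch` (half-torus, aorta-like arch), or a `bifurcating_tree`
#' (pulmonary-trunk-like: one trunk splitting into two daughters whose radii
#' follow Murray's law, r_d = r_t * 2^(-1/3)). The non-contrast rendering has
#' deliberately low vessel/background contrast, emulating how faint vessel
#' boundaries are without contrast agent; the contrast rendering is bright
#' enough to saturate the standard soft-tissue display window.
#'
#' @param geometry `"straight_tube"`, `"torus_arch"` or `"bifurcating_tree"`.
#' @param tube_radius_mm vessel (trunk) radius in mm.
#' @param arch_radius_mm radius of the arch centreline circle (torus only).
#' @param branch_angle_deg full opening angle between the two daughters
#'   (tree only).
#' @param vessel_hu_nc,vessel_hu_ce vessel intensity in HU for the
#'   non-contrast and contrast renderings; must satisfy
#'   `vessel_hu_ce > vessel_hu_nc >= background_hu`.
#' @param background_hu background intensity in HU.
#' @param noise_sigma_hu standard deviation of additive Gaussian noise (HU).
#' @param blur_sigma_vox partial-volume blur (scanner PSF surrogate) in
#'   voxels, applied to the vessel indicator before intensity scaling.
#' @param spacing_mm voxel spacing triple (mm).
#' @param grid_shape voxel grid extent triple.
#' @param seed integer seed; all randomness of one rendered sample flows
#'   from it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(geometry = c("straight_tube", "torus_arch", "bifurcating_tree"),
                         tube_radius_mm = 5, arch_radius_mm = 15,
                         branch_angle_deg = 70,
                         vessel_hu_nc = 60, vessel_hu_ce = 300,
                         background_hu = 0, noise_sigma_hu = 20,
                         blur_sigma_vox = 0.5,
                         spacing_mm = c(1, 1, 1), grid_shape = c(64, 64, 64),
                         seed = 1L) {
  geometry <- match.arg(geometry)
  if (!(vessel_hu_ce > vessel_hu_nc && vessel_hu_nc >= background_hu))
    stop("need vessel_hu_ce > vessel_hu_nc >= background_hu")
  if (tube_radius_mm <= 0) stop("tube_radius_mm must be positive")
  if (noise_sigma_hu < 0) stop("noise_sigma_hu must be nonnegative")
  structure(list(geometry = geometry, tube_radius_mm = tube_radius_mm,
                 arch_radius_mm = arch_radius_mm,
                 branch_angle_deg = branch_angle_deg,
                 vessel_hu_nc = vessel_hu_nc, vessel_hu_ce = vessel_hu_ce,
                 background_hu = background_hu,
                 noise_sigma_hu = noise_sigma_hu,
                 blur_sigma_vox = blur_sigma_vox,
                 spacing_mm = rep(as.numeric(spacing_mm), length.out = 3),
                 grid_shape = as.integer(rep(grid_shape, length.out = 3)),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Analytic centreline(s) of a phantom, as a list of branches; each branch is
# a list(points = n x 3 mm matrix, radius_mm). Also returns named anchor
# points (e.g. the bifurcation).
phantom_centerline <- function(spec) {
  sp <- spec$spacing_mm
  gs <- spec$grid_shape
  ext <- (gs - 1) * sp                      # world extent (voxel centres)
  ctr <- ext / 2
  r <- spec$tube_radius_mm
  margin <- 2 * max(sp) + r
  step <- min(sp) / 4
  branches <- list()
  anchors <- list()
  if (spec$geometry == "straight_tube") {
    z <- seq(2 * max(sp), ext[3] - 2 * max(sp), by = step)
    pts <- cbind(ctr[1], ctr[2], z)
    branches[[1]] <- list(points = pts, radius_mm = r)
    anchors$tube_start <- pts[1, ]
    anchors$tube_end <- pts[nrow(pts), ]
  } else if (spec$geometry == "torus_arch") {
    R <- spec$arch_radius_mm
    if (R + r > min(ctr[1], ext[1] - ctr[1]) - 2 * max(sp) ||
        R + r > ext[3] - margin)
      stop("torus arch (R + r = ", R + r, " mm) exceeds the grid")
    z0 <- margin
    th <- seq(0, pi, by = step / R)
    pts <- cbind(ctr[1] + R * cos(th), ctr[2], z0 + R * sin(th))
    branches[[1]] <- list(points = pts, radius_mm = r)
    anchors$arch_start <- pts[1, ]
    anchors$arch_end <- pts[nrow(pts), ]
  } else {  # bifurcating_tree
    rd <- r * 2^(-1 / 3)
    half <- spec$branch_angle_deg / 2 * pi / 180
    z_bif <- ext[3] * 0.45
    zt <- seq(2 * max(sp), z_bif, by = step)
    trunk <- cbind(ctr[1], ctr[2], zt)
    bif <- c(ctr[1], ctr[2], z_bif)
    # daughters in the x-z plane
    len_d <- min((ext[3] - margin - z_bif) / cos(half),
                 (ctr[1] - margin) / sin(half))
    if (len_d <= 0) stop("bifurcating tree exceeds the grid")
    t_d <- seq(0, len_d, by = step)
    d1 <- cbind(bif[1] + sin(half) * t_d, bif[2], bif[3] + cos(half) * t_d)
    d2 <- cbind(bif[1] - sin(half) * t_d, bif[2], bif[3] + cos(half) * t_d)
    branches[[1]] <- list(points = trunk, radius_mm = r)
    branches[[2]] <- list(points = d1, radius_mm = rd)
    branches[[3]] <- list(points = d2, radius_mm = rd)
    anchors$bifurcation <- bif
  }
  list(branches = branches, anchors = anchors)
}

# Distance-based rasterization: voxel centres within radius of the polyline
# (capsule distance). Free ends are cut flat by `cap_start` / `cap_end` so a
# half-arch mask matches the analytic half-torus volume exactly (no
# spherical end caps).
rasterize_branch <- function(mask, spec, pts, radius_mm,
                             cap_start = TRUE, cap_end = TRUE) {
  sp <- spec$spacing_mm
  gs <- spec$grid_shape
  n <- nrow(pts)
  branch <- array(FALSE, dim = gs)
  seg_from <- pts[-n, , drop = FALSE]
  seg_to <- pts[-1, , drop = FALSE]
  # process in chunks of segments sharing a bounding box
  chunk <- 8L
  for (s0 in seq(1, n - 1, by = chunk)) {
    s1 <- min(n - 1, s0 + chunk - 1L)
    lo <- pmin(apply(seg_from[s0:s1, , drop = FALSE], 2, min),
               apply(seg_to[s0:s1, , drop = FALSE], 2, min)) - radius_mm - max(sp)
    hi <- pmax(apply(seg_from[s0:s1, , drop = FALSE], 2, max),
               apply(seg_to[s0:s1, , drop = FALSE], 2, max)) + radius_mm + max(sp)
    ilo <- pmax(1L, floor(lo / sp) + 1L)
    ihi <- pmin(gs, ceiling(hi / sp) + 1L)
    if (any(ilo > ihi)) next
    gx <- (ilo[1]:ihi[1] - 1) * sp[1]
    gy <- (ilo[2]:ihi[2] - 1) * sp[2]
    gz <- (ilo[3]:ihi[3] - 1) * sp[3]
    px <- rep(gx, times = length(gy) * length(gz))
    py <- rep(rep(gy, each = length(gx)), times = length(gz))
    pz <- rep(gz, each = length(gx) * length(gy))
    d2 <- rep(Inf, length(px))
    for (s in s0:s1) {
      a <- seg_from[s, ]; b <- seg_to[s, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) rep(0, length(px)) else
        pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] +
                           (pz - a[3]) * ab[3]) / len2))
      dx <- px - (a[1] + t * ab[1])
      dy <- py - (a[2] + t * ab[2])
      dz <- pz - (a[3] + t * ab[3])
      d2 <- pmin(d2, dx * dx + dy * dy + dz * dz)
    }
    inside <- array(d2 <= radius_mm^2,
                    dim = c(length(gx), length(gy), length(gz)))
    branch[ilo[1]:ihi[1], ilo[2]:ihi[2], ilo[3]:ihi[3]] <-
      branch[ilo[1]:ihi[1], ilo[2]:ihi[2], ilo[3]:ihi[3]] | inside
  }
  cut_cap <- function(branch, endpt, outward) {
    rr <- radius_mm + 2 * max(sp)
    ilo <- pmax(1L, as.integer(floor((endpt - rr) / sp) + 1L))
    ihi <- pmin(gs, as.integer(ceiling((endpt + rr) / sp) + 1L))
    gx <- (ilo[1]:ihi[1] - 1) * sp[1]
    gy <- (ilo[2]:ihi[2] - 1) * sp[2]
    gz <- (ilo[3]:ihi[3] - 1) * sp[3]
    px <- rep(gx, times = length(gy) * length(gz)) - endpt[1]
    py <- rep(rep(gy, each = length(gx)), times = length(gz)) - endpt[2]
    pz <- rep(gz, each = length(gx) * length(gy)) - endpt[3]
    beyond <- (px * outward[1] + py * outward[2] + pz * outward[3]) > 0 &
      (px^2 + py^2 + pz^2) <= rr^2
    sub <- branch[ilo[1]:ihi[1], ilo[2]:ihi[2], ilo[3]:ihi[3]]
    sub[array(beyond, dim = dim(sub))] <- FALSE
    branch[ilo[1]:ihi[1], ilo[2]:ihi[2], ilo[3]:ihi[3]] <- sub
    branch
  }
  dir1 <- pts[1, ] - pts[2, ]
  dirn <- pts[n, ] - pts[n - 1, ]
  if (cap_start) branch <- cut_cap(branch, pts[1, ], dir1 / sqrt(sum(dir1^2)))
  if (cap_end) branch <- cut_cap(branch, pts[n, ], dirn / sqrt(sum(dirn^2)))
  mask | branch
}

#' Render a synthetic vessel phantom
#'
#' Produces the paired non-contrast and contrast-enhanced HU volumes, the
#' ground-truth binary mask (voxel centres within `tube_radius_mm` of the
#' analytic centreline), and the analytic truth record. Both intensity
#' volumes are `background_hu` plus the vessel excess intensity modulated by
#' a Gaussian partial-volume blur of the vessel indicator, plus
#' `N(0, noise_sigma_hu^2)` voxel noise drawn from `spec$seed` (the two
#' renderings share vessel geometry but have independent noise).
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_sample`: list with elements `nc`, `ce` (HU
#'   `ct_volume`s), `mask` (binary `ct_volume`), and `truth` (spec, analytic
#'   centreline branches, anchors, true diameter in mm).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cl <- phantom_centerline(spec)
  gs <- spec$grid_shape
  mask <- array(FALSE, dim = gs)
  tree <- spec$geometry == "bifurcating_tree"
  for (i in seq_along(cl$branches)) {
    br <- cl$branches[[i]]
    # in the tree, branch junction ends stay rounded so the union is smooth
    mask <- rasterize_branch(mask, spec, br$points, br$radius_mm,
                             cap_start = !(tree && i > 1),
                             cap_end = !(tree && i == 1))
  }
  if (!any(mask)) stop("phantom mask is empty; geometry outside the grid?")
  ind <- array(as.numeric(mask), dim = gs)
  pv <- gauss3d(ind, spec$blur_sigma_vox)
  set.seed(spec$seed)
  mknoise <- function() array(stats::rnorm(prod(gs), 0, spec$noise_sigma_hu), dim = gs)
  nc <- spec$background_hu + (spec$vessel_hu_nc - spec$background_hu) * pv + mknoise()
  ce <- spec$background_hu + (spec$vessel_hu_ce - spec$background_hu) * pv + mknoise()
  sp <- spec$spacing_mm
  structure(list(
    nc = ct_volume(nc, spacing = sp, intensity_kind = "HU"),
    ce = ct_volume(ce, spacing = sp, intensity_kind = "HU"),
    mask = ct_volume(ind, spacing = sp, intensity_kind = "mask"),
    truth = list(spec = spec, centerline = cl$branches, anchors = cl$anchors,
                 diameter_mm = 2 * spec$tube_radius_mm)),
    class = "phantom_sample")
}

# Draw jittered specs deterministically from a seed. `jitter` is a named list
# of c(min, max) ranges over phantom_spec numeric fields.
jitter_specs <- function(n, base_spec, jitter = list(), seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    for (field in names(jitter)) {
      rng <- jitter[[field]]
      if (length(rng) != 2L || rng[2] < rng[1])
        stop("invalid jitter range for ", field)
      sp[[field]] <- stats::runif(1, rng[1], rng[2])
    }
    sp$seed <- as.integer((seed * 1009L + i * 97L) %% .Machine$integer.max)
    class(sp) <- "phantom_spec"
    sp
  })
}

#' Generate phantoms in memory
#'
#' @param n number of samples.
#' @param base_spec template [phantom_spec()].
#' @param jitter named list of `c(min, max)` ranges for numeric spec fields
#'   (e.g. `list(tube_radius_mm = c(3, 6))`); one value per sample is drawn
#'   uniformly.
#' @param seed integer; drives both jitter draws and per-sample noise seeds.
#' @return List of `phantom_sample` objects.
#' @export
generate_phantoms <- function(n, base_spec, jitter = list(), seed = 1L) {
  specs <- jitter_specs(n, base_spec, jitter, seed)
  lapply(specs, render_phantom)
}

# Largest-remainder split of n into parts proportional to `fractions`.
split_counts <- function(n, fractions) {
  fractions <- fractions / sum(fractions)
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom samples as NIfTI triples (`*_nc.nii.gz`,
#' `*_ce.nii.gz`, `*_mask.nii.gz`) plus a manifest (CSV and JSON) recording
#' each sample's spec fields, its true diameter (exactly
#' `2 * tube_radius_mm`), and a train/val/test split assignment.
#'
#' @inheritParams generate_phantoms
#' @param out_dir output directory (created if missing).
#' @param split fractions for the train/val/test assignment; the default
#'   reproduces an 80/20/20-out-of-120 style division.
#' @return The manifest as a data.frame (invisibly written to
#'   `manifest.csv` / `manifest.json`).
#' @export
generate_dataset <- function(n, base_spec, jitter = list(), seed = 1L,
                             out_dir, split = c(train = 80, val = 20, test = 20)) {
  if (n < 1) stop("n must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- jitter_specs(n, base_spec, jitter, seed)
  counts <- split_counts(n, split)
  assignment <- rep(names(split), counts)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sm <- render_phantom(specs[[i]])
    id <- sprintf("phantom_%03d", i)
    paths <- file.path(out_dir, paste0(id, c("_nc.nii.gz", "_ce.nii.gz", "_mask.nii.gz")))
    write_nifti_volume(sm$nc, paths[1])
    write_nifti_volume(sm$ce, paths[2])
    write_nifti_volume(sm$mask, paths[3])
    sp <- specs[[i]]
    rows[[i]] <- data.frame(
      id = id, geometry = sp$geometry, tube_radius_mm = sp$tube_radius_mm,
      true_diameter_mm = 2 * sp$tube_radius_mm,
      arch_radius_mm = sp$arch_radius_mm,
      branch_angle_deg = sp$branch_angle_deg,
      vessel_hu_nc = sp$vessel_hu_nc, vessel_hu_ce = sp$vessel_hu_ce,
      background_hu = sp$background_hu, noise_sigma_hu = sp$noise_sigma_hu,
      seed = sp$seed, split = assignment[i],
      nc = basename(paths[1]), ce = basename(paths[2]), mask = basename(paths[3]),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}
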