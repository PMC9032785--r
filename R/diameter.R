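#' Centerline objects
#'
#' An ordered, arc-length-parameterized 3D polyline in millimetres through a
#' vessel, with unit tangents per point.
#'
#' @param points n x 3 matrix of mm coordinates.
#' @return A `centerline` object with `points`, `tangents`, `arclength`.
#' @export
new_centerline <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  if (n < 2L) stop("a centerline needs at least 2 points")
  seg <- diff(points)
  seglen <- sqrt(rowSums(seg^2))
  keep <- c(TRUE, seglen > 1e-9)
  points <- points[keep, , drop = FALSE]
  n <- nrow(points)
  seg <- diff(points)
  seglen <- sqrt(rowSums(seg^2))
  arclength <- c(0, cumsum(seglen))
  # central differences where possible, one-sided at the ends
  tang <- matrix(NA_real_, n, 3)
  tang[1, ] <- seg[1, ]
  tang[n, ] <- seg[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = points, tangents = tang, arclength = arclength),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arclength %.1f mm\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

# Linear interpolation of position and tangent at arclength s (vectorized).
interp_centerline <- function(cl, s) {
  al <- cl$arclength
  if (any(s < al[1] - 1e-9) || any(s > al[length(al)] + 1e-9))
    stop(sprintf("arclength position outside centerline (available 0 to %.2f mm)",
                 max(al)))
  pts <- vapply(1:3, function(j) stats::approx(al, cl$points[, j], xout = s,
                                               rule = 2)$y, numeric(length(s)))
  tg <- vapply(1:3, function(j) stats::approx(al, cl$tangents[, j], xout = s,
                                              rule = 2)$y, numeric(length(s)))
  pts <- matrix(pts, ncol = 3)
  tg <- matrix(tg, ncol = 3)
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pts, tangents = tg)
}

moving_average <- function(m, w) {
  if (w < 2 || nrow(m) < w) return(m)
  out <- m
  n <- nrow(m)
  h <- w %/% 2
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(m[lo:hi, , drop = FALSE])
  }
  out
}

mask_data <- function(mask) {
  if (inherits(mask, "ct_volume")) mask else
    ct_volume(mask, intensity_kind = "mask")
}

# Sub-voxel re-centring: replace each centerline point by the centroid of
# its perpendicular cross-section (skeleton/tracker points sit on the voxel
# lattice, up to half a voxel off the true axis; the section centroid of a
# tubular lumen recovers the axis without longitudinal or curvature pull).
recenter_centerline <- function(v, cl, iterations = 2) {
  for (it in seq_len(iterations)) {
    pts <- cl$points
    for (i in seq_len(nrow(pts))) {
      cs <- tryCatch(cross_section(v, pts[i, ], cl$tangents[i, ]),
                     error = function(e) NULL)
      if (!is.null(cs)) pts[i, ] <- cs$centroid_mm
    }
    cl <- new_centerline(pts)
  }
  # a light final average removes the sub-voxel centroid-quantization
  # jitter, which otherwise inflates the arclength
  new_centerline(moving_average(cl$points, 3))
}

#' Aorta centerline by erosion-constrained tracking
#'
#' The mask is eroded so the centerline search is confined to the vessel
#' core; the tracker then steps repeatedly to the candidate core voxel whose
#' step direction is most orthogonal to the local vessel-surface normal
#' (i.e. most parallel to the wall, hence along the vessel), estimated from
#' the gradient of the Euclidean distance transform. Tracking stops when the
#' core is exhausted.
#'
#' @param mask binary mask `ct_volume` (or array).
#' @param seed_mm optional mm start point near the heart exit; snapped to
#'   the nearest core voxel. Default: the inferior (smallest z) end of the
#'   core, breaking ties toward larger x (the ascending limb in this
#'   package's arch convention).
#' @param erosion_radius erosion radius in voxels (default 2).
#' @param step_vox tracker step radius in voxels (default 3).
#' @param smooth_window moving-average window (points) for the final
#'   polyline.
#' @return A [new_centerline()] object.
#' @export
centerline_aorta <- function(mask, seed_mm = NULL, erosion_radius = 2,
                             step_vox = 3, smooth_window = 5) {
  v <- mask_data(mask)
  if (!any(v$data > 0)) stop("mask is empty")
  d2 <- edt_sq(v$data, c(1, 1, 1))  # voxel-unit distance for erosion
  core <- sqrt(d2) > erosion_radius
  if (!any(core))
    stop("eroded region is empty (vessel thinner than the erosion radius ",
         erosion_radius, "); retry with a smaller erosion_radius")
  d2mm <- edt_sq(v$data, v$spacing)
  dist_mm <- sqrt(d2mm)
  grad_at <- function(ijk) {
    d <- dim(v$data)
    g <- numeric(3)
    for (ax in 1:3) {
      lo <- ijk; hi <- ijk
      lo[ax] <- max(1, ijk[ax] - 1); hi[ax] <- min(d[ax], ijk[ax] + 1)
      g[ax] <- (dist_mm[hi[1], hi[2], hi[3]] - dist_mm[lo[1], lo[2], lo[3]]) /
        ((hi[ax] - lo[ax]) * v$spacing[ax])
    }
    g
  }
  core_idx <- which(core, arr.ind = TRUE)
  core_mm <- voxel_to_world(v, core_idx)
  nrm <- t(apply(core_idx, 1, grad_at))
  nn <- sqrt(rowSums(nrm^2))
  nn[nn == 0] <- 1
  nrm <- nrm / nn
  if (is.null(seed_mm)) {
    zmin <- min(core_idx[, 3])
    bottom <- which(core_idx[, 3] <= zmin + step_vox)
    start <- bottom[which.max(core_idx[bottom, 1])]
  } else {
    d2s <- rowSums(sweep(core_mm, 2, as.numeric(seed_mm))^2)
    start <- which.min(d2s)
  }
  visited <- logical(nrow(core_idx))
  step_mm <- step_vox * max(v$spacing)
  mark <- function(p) {
    visited[rowSums(sweep(core_mm, 2, p)^2) <= step_mm^2] <<- TRUE
  }
  candidates_near <- function(p, prev_dir, mult) {
    dd <- sqrt(rowSums(sweep(core_mm, 2, p)^2))
    cand <- which(!visited & dd > 1e-6 & dd <= mult * step_mm)
    if (length(cand) == 0L) return(NULL)
    dirs <- sweep(core_mm[cand, , drop = FALSE], 2, p) / dd[cand]
    if (!is.null(prev_dir)) {
      fwd <- dirs %*% prev_dir > 0
      if (!any(fwd)) return(NULL)
      cand <- cand[fwd]; dirs <- dirs[fwd, , drop = FALSE]
    }
    list(cand = cand, dirs = dirs)
  }
  track_from <- function(p, prev_dir) {
    path <- list()
    first_dir <- NULL
    for (iter in seq_len(10000L)) {
      g <- candidates_near(p, prev_dir, 1.5)
      if (is.null(g)) g <- candidates_near(p, prev_dir, 2.5)  # bridge gaps
      if (is.null(g)) break
      score <- abs(rowSums(g$dirs * nrm[g$cand, , drop = FALSE]))
      if (!is.null(prev_dir))  # small turn penalty breaks near-ties
        score <- score + 0.3 * (1 - g$dirs %*% prev_dir)
      pick <- which.min(score)
      newp <- core_mm[g$cand[pick], ]
      prev_dir <- g$dirs[pick, ]
      if (is.null(first_dir)) first_dir <- prev_dir
      mark(newp)
      path[[length(path) + 1L]] <- newp
      p <- newp
    }
    list(path = path, first_dir = first_dir)
  }
  # track both ways from the seed (it need not be a vessel end) and join
  p0 <- core_mm[start, ]
  mark(p0)
  fwd <- track_from(p0, NULL)
  bwd <- if (is.null(fwd$first_dir)) list(path = list()) else
    track_from(p0, -fwd$first_dir)
  path <- c(rev(bwd$path), list(p0), fwd$path)
  if (length(path) < 3L)
    warning("tracker stalled after ", length(path), " points; partial centerline")
  # smoothing first (it pulls the noisy terminal lattice points inward);
  # the end extension below then walks back out to the true vessel ends
  pts <- moving_average(do.call(rbind, path), smooth_window)
  # the eroded core stops short of the vessel ends; walk each end onward
  # through the full mask, re-centring on the cross-section centroid, until
  # the lumen runs out
  extend_end <- function(pts, flip) {
    if (flip) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    n <- nrow(pts)
    # end tangent from the principal direction of the last few points
    m <- max(3L, min(5L, n))
    tail_pts <- pts[(n - m + 1L):n, , drop = FALSE]
    pc <- stats::prcomp(tail_pts, center = TRUE)
    tdir <- pc$rotation[, 1]
    if (sum(tdir * (pts[n, ] - pts[n - m + 1L, ])) < 0) tdir <- -tdir
    p <- pts[n, ]
    ref <- tryCatch(cross_section(v, p, tdir), error = function(e) NULL)
    for (k in seq_len(50L)) {
      q <- p + tdir * max(v$spacing)
      ijk <- round(world_to_voxel(v, q))
      d <- dim(v$data)
      if (any(ijk < 1) || any(ijk > d) || v$data[ijk] <= 0) break
      cs <- tryCatch(cross_section(v, q, tdir), error = function(e) NULL)
      if (is.null(cs)) break
      # stop if the section degenerates (oblique cuts at an open boundary)
      if (!is.null(ref) &&
          (cs$area_mm2 < 0.3 * ref$area_mm2 || cs$area_mm2 > 2 * ref$area_mm2))
        break
      # stop unless the re-centred point makes real forward progress
      if (sum((cs$centroid_mm - p) * tdir) < 0.3 * max(v$spacing)) break
      pts <- rbind(pts, cs$centroid_mm)
      p <- q
    }
    if (flip) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    pts
  }
  pts <- extend_end(pts, flip = FALSE)
  pts <- extend_end(pts, flip = TRUE)
  recenter_centerline(v, new_centerline(pts))
}

# Cluster branch voxels (>= 3 skeleton neighbours) into junctions by
# 26-adjacency; returns cluster centroids in voxel coordinates.
cluster_branch_voxels <- function(idx) {
  n <- nrow(idx)
  if (n == 0L) return(idx)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (max(abs(idx[i, ] - idx[j, ])) <= 1) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  t(vapply(unique(comp), function(cp)
    colMeans(idx[comp == cp, , drop = FALSE]), numeric(3)))
}

#' Pulmonary-artery centerline by skeletonization
#'
#' Topologically thins the mask to a curve skeleton, builds the skeleton
#' adjacency graph, detects branch points (skeleton voxels with at least
#' three neighbours, clustered into junctions), and takes the main vessel as
#' the graph path from the trunk endpoint (the endpoint farthest from any
#' branch point) to the first branch point reached. The path is smoothed by
#' cubic smoothing splines in each coordinate against arclength and
#' re-sampled at uniform arclength steps, oriented from the branch point
#' toward the trunk (s = 0 at the branch point).
#'
#' @param mask binary mask `ct_volume` (or array), one connected vessel
#'   (largest component is used, with a warning, if not).
#' @param knot_mm smoothing-spline knot spacing (mm).
#' @param step_mm resampling step of the smoothed centerline (mm).
#' @param prune_mm skeleton leaf branches shorter than this are discarded as
#'   thinning artefacts before junction detection; the default (`NULL`)
#'   uses 1.2 times the maximal inscribed radius of the vessel.
#' @return list with `centerline` (a [new_centerline()]), `branch_points`
#'   (matrix of mm junction coordinates, possibly 0 rows), and
#'   `raw_length_mm` (arclength of the unsmoothed skeleton path).
#' @export
centerline_pa <- function(mask, knot_mm = 5, step_mm = 0.5, prune_mm = NULL) {
  v <- mask_data(mask)
  if (!any(v$data > 0)) stop("mask is empty")
  lab <- label3d(v$data, 26L)
  nc <- max(lab)
  m <- v$data
  if (nc > 1L) {
    warning("mask has ", nc, " connected components; using the largest")
    keep <- which.max(tabulate(lab))
    m <- (lab == keep) * 1
    dim(m) <- dim(v$data)
  }
  dist_mm <- sqrt(edt_sq(m, v$spacing))
  if (is.null(prune_mm)) prune_mm <- 1.2 * max(dist_mm)
  sk <- skeletonize3d(m)
  idx <- which(sk > 0, arr.ind = TRUE)
  nv <- nrow(idx)
  if (nv < 2L) stop("skeleton degenerated to fewer than 2 voxels")
  vid <- array(0L, dim = dim(sk))
  vid[idx] <- seq_len(nv)
  edges <- list()
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  d <- dim(sk)
  for (o in seq_len(nrow(off))) {
    nb <- sweep(idx, 2, off[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    j <- rep(0L, nv)
    j[ok] <- vid[nb[ok, , drop = FALSE]]
    src <- which(j > seq_len(nv))
    if (length(src))
      edges[[length(edges) + 1L]] <- cbind(src, j[src])
  }
  el <- do.call(rbind, edges)
  w <- sqrt(rowSums((sweep(idx[el[, 1], , drop = FALSE] - idx[el[, 2], , drop = FALSE],
                           2, v$spacing, "*"))^2))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  igraph::E(g)$weight <- w
  # the thinned set can retain short braided double strands; the minimum
  # spanning tree breaks their cycles into leaf twigs, which the spur
  # pruning below then removes, leaving only anatomical junctions
  g <- igraph::mst(g)
  # prune short leaf spurs (thinning artefacts near tube caps) so that only
  # anatomical branches survive as junctions
  repeat {
    deg_sk <- igraph::degree(g)
    branch_v <- which(deg_sk >= 3)
    endpoints <- which(deg_sk == 1)
    if (length(branch_v) == 0L || length(endpoints) == 0L) break
    dmat <- igraph::distances(g, v = endpoints, to = branch_v)
    near <- apply(dmat, 1, min)
    spur <- which(near < prune_mm)
    if (length(spur) == 0L) break
    del <- integer(0)
    for (si in spur) {
      e <- endpoints[si]
      bi <- branch_v[which.min(dmat[si, ])]
      pth <- as.integer(igraph::shortest_paths(g, from = e, to = bi)$vpath[[1]])
      del <- c(del, setdiff(pth, bi))
    }
    g <- igraph::delete_edges(g, unlist(igraph::incident_edges(g, unique(del))))
  }
  deg_sk <- igraph::degree(g)
  branch_v <- which(deg_sk >= 3)
  endpoints <- which(deg_sk == 1)
  branch_pts_vox <- cluster_branch_voxels(idx[branch_v, , drop = FALSE])
  if (length(branch_v) == 0L || length(endpoints) == 0L) {
    warning("no branch point found; treating the whole skeleton as the main vessel")
    dia <- igraph::get_diameter(g)
    path_v <- as.integer(dia)
  } else {
    # the main vessel (pulmonary trunk) is the widest limb: pick the
    # endpoint with the largest local inscribed radius, then measure to the
    # first junction on the way
    ep_radius <- dist_mm[idx[endpoints, , drop = FALSE]]
    trunk_end <- endpoints[which.max(ep_radius)]
    dvec <- igraph::distances(g, v = trunk_end, to = branch_v)[1, ]
    first_branch <- branch_v[which.min(dvec)]
    sp <- igraph::shortest_paths(g, from = first_branch, to = trunk_end)
    path_v <- as.integer(sp$vpath[[1]])
  }
  pts_vox <- idx[path_v, , drop = FALSE]
  pts <- voxel_to_world(v, pts_vox)
  raw_len <- sum(sqrt(rowSums(diff(pts)^2)))
  # suppress lattice zigzag before parameterizing by arclength
  pts <- moving_average(pts, 5)
  seg <- sqrt(rowSums(diff(pts)^2))
  s_raw <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  s_raw <- unique(s_raw)
  raw_smooth_len <- max(s_raw)
  n <- nrow(pts)
  if (n >= 8 && raw_smooth_len > 4 * step_mm) {
    df <- max(4, min(n - 1, round(raw_smooth_len / knot_mm) + 3))
    s_new <- seq(0, raw_smooth_len, by = step_mm)
    sm <- vapply(1:3, function(j) {
      fit <- stats::smooth.spline(s_raw, pts[, j], df = df)
      stats::predict(fit, s_new)$y
    }, numeric(length(s_new)))
    cl <- new_centerline(matrix(sm, ncol = 3))
  } else {
    cl <- new_centerline(pts)
  }
  cl <- recenter_centerline(v, cl)
  bp_mm <- if (nrow(branch_pts_vox) > 0)
    voxel_to_world(v, branch_pts_vox) else matrix(numeric(0), 0, 3)
  list(centerline = cl, branch_points = bp_mm, raw_length_mm = raw_len)
}

orthonormal_basis <- function(normal) {
  normal <- normal / sqrt(sum(normal^2))
  e <- diag(3)[, which.min(abs(normal))]
  u <- c(normal[2] * e[3] - normal[3] * e[2],
         normal[3] * e[1] - normal[1] * e[3],
         normal[1] * e[2] - normal[2] * e[1])
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  list(u = u, v = v, normal = normal)
}

#' Vessel cross-section on a plane perpendicular to the centerline
#'
#' Samples the mask by nearest-neighbour membership on a 2D grid in the
#' plane through `center_mm` orthogonal to `normal`, keeps the in-plane
#' connected component containing the centre, and reports its area and
#' equivalent-circle diameter `2 * sqrt(area / pi)`.
#'
#' @param mask binary mask `ct_volume`.
#' @param center_mm mm point on the centerline (must lie inside the mask).
#' @param normal unit tangent (plane normal).
#' @param plane_res in-plane sampling resolution (mm); default half the
#'   smallest voxel spacing.
#' @param max_radius_mm half-extent of the sampling plane (mm).
#' @return A `cross_section` list: `center`, `normal`, `area_mm2`,
#'   `equivalent_diameter_mm`.
#' @export
cross_section <- function(mask, center_mm, normal, plane_res = NULL,
                          max_radius_mm = 25) {
  v <- mask_data(mask)
  if (is.null(plane_res)) plane_res <- min(v$spacing) / 2
  ob <- orthonormal_basis(normal)
  ax <- seq(-max_radius_mm, max_radius_mm, by = plane_res)
  na <- length(ax)
  a <- rep(ax, times = na)
  b <- rep(ax, each = na)
  pts <- outer(a, ob$u) + outer(b, ob$v)
  pts <- sweep(pts, 2, as.numeric(center_mm), "+")
  ijk <- round(world_to_voxel(v, pts))
  d <- dim(v$data)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  memb <- logical(na * na)
  memb[ok] <- v$data[ijk[ok, , drop = FALSE]] > 0
  ctr_pix <- which(a == 0 & b == 0)
  if (!memb[ctr_pix]) stop("cross-section center lies outside the mask")
  plane <- array(as.numeric(memb), dim = c(na, na, 1L))
  lab <- label3d(plane, 26L)
  keep <- lab[ctr_pix]
  inplane <- lab == keep
  area <- sum(inplane) * plane_res^2
  # in-plane centroid of the section, mapped back to 3D (used to re-centre
  # centerline points on the lumen)
  centroid <- as.numeric(center_mm) + mean(a[inplane]) * ob$u +
    mean(b[inplane]) * ob$v
  structure(list(center = as.numeric(center_mm), normal = ob$normal,
                 area_mm2 = area,
                 equivalent_diameter_mm = 2 * sqrt(area / pi),
                 centroid_mm = centroid,
                 plane_res = plane_res),
            class = "cross_section")
}

#' Mean vessel diameter over a measurement window
#'
#' Samples cross-sections perpendicular to the centerline at arclength
#' positions `start, start + step, ..., <= end` and averages their
#' equivalent diameters. The conventional windows are 5-25 mm from the
#' heart-exit end for the aorta and 5-15 mm from the branch point toward
#' the trunk for the pulmonary artery, both at 0.4 mm steps.
#'
#' @param mask binary mask `ct_volume`.
#' @param cl a [new_centerline()] (s = 0 at the anatomical anchor).
#' @param window_mm `(start, end)` arclength window in mm.
#' @param step_mm sampling interval (default 0.4 mm).
#' @param vessel label stored in the report.
#' @param ... passed to [cross_section()].
#' @return A `diameter_report`: `vessel`, `window_mm`, `step_mm`, `sections`
#'   (data.frame with per-section arclength, area, diameter), and
#'   `mean_diameter_mm`.
#' @export
mean_diameter <- function(mask, cl, window_mm, step_mm = 0.4,
                          vessel = c("aorta", "pulmonary_artery"), ...) {
  vessel <- match.arg(vessel)
  if (step_mm <= 0) stop("step_mm must be positive")
  if (window_mm[2] < window_mm[1]) stop("window must satisfy start <= end")
  if (window_mm[2] > max(cl$arclength) + 1e-9)
    stop(sprintf("window end %.1f mm exceeds the centerline arclength (%.1f mm available)",
                 window_mm[2], max(cl$arclength)))
  s <- seq(window_mm[1], window_mm[2], by = step_mm)
  ip <- interp_centerline(cl, s)
  secs <- lapply(seq_along(s), function(i)
    cross_section(mask, ip$points[i, ], ip$tangents[i, ], ...))
  df <- data.frame(
    arclength_mm = s,
    area_mm2 = vapply(secs, `[[`, numeric(1), "area_mm2"),
    equivalent_diameter_mm = vapply(secs, `[[`, numeric(1), "equivalent_diameter_mm"))
  structure(list(vessel = vessel, window_mm = window_mm, step_mm = step_mm,
                 sections = df, mean_diameter_mm = mean(df$equivalent_diameter_mm)),
            class = "diameter_report")
}

#' @export
print.diameter_report <- function(x, ...) {
  cat(sprintf("<diameter_report> %s: mean diameter %.2f mm over %d sections (window %.1f-%.1f mm, step %.2f mm)\n",
              x$vessel, x$mean_diameter_mm, nrow(x$sections),
              x$window_mm[1], x$window_mm[2], x$step_mm))
  invisible(x)
}

#' Write a diameter report to JSON and CSV
#'
#' @param report a `diameter_report`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_diameter_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  if (!is.null(csv_path))
    utils::write.csv(report$sections, csv_path, row.names = FALSE)
  invisible(report)
}

#' Pulmonary-artery to aorta diameter ratio
#'
#' The PA/Ao ratio is a radiologic marker of pulmonary hypertension.
#'
#' @param d_pa,d_ao mean diameters in mm; `d_ao` must be positive.
#' @return `d_pa / d_ao`.
#' @export
pa_ao_ratio <- function(d_pa, d_ao) {
  if (d_ao <= 0) stop("aorta diameter must be positive")
  d_pa / d_ao
}
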