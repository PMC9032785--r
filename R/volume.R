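#' Construct a CT volume
#'
#' A `ct_volume` is a 3D scalar grid with voxel spacing, world origin, and an
#' intensity kind. Voxel `(i, j, k)` (1-based) has world coordinate
#' `origin + (c(i, j, k) - 1) * spacing` in millimetres; arrays are stored in
#' R's column-major `(x, y, z)` order, matching NIfTI layout.
#'
#' @param data numeric 3D array.
#' @param spacing positive numeric length-3, millimetres per voxel.
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @param intensity_kind `"HU"` for calibrated Hounsfield units,
#'   `"normalized"` for values in \[0, 1\] (e.g. after [window_normalize()]),
#'   or `"mask"` for binary masks.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      intensity_kind = c("HU", "normalized", "mask")) {
  intensity_kind <- match.arg(intensity_kind)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (intensity_kind == "normalized") {
    rng <- range(data)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("normalized volumes must have values in [0, 1]")
  }
  if (intensity_kind == "mask" && !all(data %in% c(0, 1)))
    stop("mask volumes must be binary (0/1)")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), intensity_kind = intensity_kind),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$intensity_kind))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

is_ct_volume <- function(x) inherits(x, "ct_volume")

#' World coordinates of voxel indices
#' @param v a [ct_volume()].
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world mm coordinates.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, v$origin, "-"), 2, v$spacing, "/") + 1
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over \pkg{RNifti}. Spacing is taken from (or written to) the
#' NIfTI `pixdim`; the origin from the `qoffset` translation.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param intensity_kind intensity kind to tag the volume with (NIfTI does not
#'   record it).
#' @return [read_nifti_volume()] returns a `ct_volume`;
#'   [write_nifti_volume()] returns `path` invisibly.
#' @export
read_nifti_volume <- function(path, intensity_kind = "HU") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  # plain array, shedding RNifti's image attributes
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  hdr <- RNifti::niftiHeader(img)
  org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  ct_volume(arr, spacing = sp, origin = org, intensity_kind = intensity_kind)
}

#' @rdname read_nifti_volume
#' @param v a `ct_volume`.
#' @export
write_nifti_volume <- function(v, path) {
  img <- RNifti::asNifti(v$data, reference = NULL)
  RNifti::pixdim(img) <- v$spacing
  hdr <- RNifti::niftiHeader(img)
  hdr$qoffset_x <- v$origin[1]; hdr$qoffset_y <- v$origin[2]
  hdr$qoffset_z <- v$origin[3]; hdr$qform_code <- 1L
  img <- RNifti::asNifti(v$data, reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- minimal DICOM series reader ----------------------------------------
# Parses DICOM Part-10 files, explicit or implicit VR little endian, pulling
# only the tags needed to assemble an axial CT series. Sequences with
# undefined length and encapsulated pixel data are not supported.

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  pos <- 133L
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) as.integer(raw[p]) + 256 * as.integer(raw[p + 1L]) +
    65536 * as.integer(raw[p + 2L]) + 16777216 * as.integer(raw[p + 3L])
  txtval <- function(from, len) {
    r <- raw[from:(from + len - 1L)]
    trimws(rawToChar(r[r != as.raw(0)]))
  }
  explicit <- TRUE
  ts <- NULL
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    in_meta <- grp == 2L
    exp_here <- if (in_meta) TRUE else explicit
    if (exp_here) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295 || (vr == "SQ"))
      stop("unsupported DICOM encoding (undefined-length/sequence) in ", path)
    val_pos <- pos + hdr
    key <- sprintf("%04x,%04x", grp, ele)
    if (key == "0002,0010") {
      ts <- txtval(val_pos, len)
      explicit <- !identical(ts, "1.2.840.10008.1.2")
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported transfer syntax ", ts, " in ", path)
    }
    if (key %in% c("0020,0032", "0020,0037", "0028,0030", "0028,1052", "0028,1053")) {
      tags[[key]] <- as.numeric(strsplit(txtval(val_pos, len), "\\\\")[[1]])
    } else if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
      tags[[key]] <- u16(val_pos)
    } else if (key == "7fe0,0010") {
      tags[["pixel_data"]] <- raw[val_pos:(val_pos + len - 1L)]
      break
    }
    pos <- val_pos + len
  }
  tags
}

#' Read an axial DICOM series as a CT volume
#'
#' Reads every file in `path`, sorts slices by their z position
#' (ImagePositionPatient), applies the rescale slope/intercept to obtain
#' Hounsfield units, and checks that the slice spacing is uniform.
#'
#' @param path directory containing the DICOM files of one axial series.
#' @param tol relative tolerance on slice-spacing uniformity.
#' @return A `ct_volume` in HU. Spacing is `(column, row, slice)` mm.
#' @export
read_dicom_series <- function(path, tol = 1e-3) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no DICOM files found in ", path)
  slices <- lapply(files, read_dicom_file)
  z <- vapply(slices, function(s) s[["0020,0032"]][3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]; files <- files[ord]
  s1 <- slices[[1]]
  rows <- s1[["0028,0010"]]; cols <- s1[["0028,0011"]]
  bits <- if (is.null(s1[["0028,0100"]])) 16L else s1[["0028,0100"]]
  signed <- !is.null(s1[["0028,0103"]]) && s1[["0028,0103"]] == 1L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  ps <- s1[["0028,0030"]]  # (row spacing = y, column spacing = x)
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(z)
    if (any(dz <= 0)) stop("duplicate or non-increasing slice positions")
    med <- stats::median(dz)
    bad <- which(abs(dz - med) > max(tol * med, 1e-6))
    if (length(bad) > 0L)
      stop("inconsistent slice spacing between slices ",
           paste(sprintf("%d-%d (gap %.4g mm, expected %.4g mm)",
                         bad, bad + 1L, dz[bad], med), collapse = ", "),
           "; files: ", paste(basename(files[c(bad, bad + 1L)]), collapse = ", "))
    slice_sp <- med
  } else slice_sp <- 1
  arr <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    px <- readBin(s$pixel_data, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
    slope <- if (is.null(s[["0028,1053"]])) 1 else s[["0028,1053"]]
    inter <- if (is.null(s[["0028,1052"]])) 0 else s[["0028,1052"]]
    # DICOM pixel data is row-major: columns vary fastest
    arr[, , k] <- matrix(px * slope + inter, nrow = cols, ncol = rows)
  }
  org <- s1[["0020,0032"]]
  if (is.null(org)) org <- c(0, 0, z[1])
  ct_volume(arr, spacing = c(ps[2], ps[1], slice_sp), origin = org,
            intensity_kind = "HU")
}

#' Resample a volume to a new voxel spacing
#'
#' The output grid has `round(dim * spacing / new_spacing)` voxels per axis;
#' intensities are interpolated at the requested order (0 = nearest, for
#' masks; 1 = trilinear, for images). The grid stays corner-aligned at the
#' centre of voxel (1,1,1), so an identity resample is voxelwise exact.
#'
#' @param v a [ct_volume()].
#' @param new_spacing target spacing in mm (length 1 or 3).
#' @param order interpolation order, 0 or 1.
#' @return A resampled `ct_volume` with the same `intensity_kind`.
#' @export
resample_volume <- function(v, new_spacing, order = 1L) {
  new_spacing <- rep(as.numeric(new_spacing), length.out = 3)
  if (any(!is.finite(new_spacing)) || any(new_spacing <= 0))
    stop("`new_spacing` must be strictly positive")
  if (!order %in% c(0L, 1L)) stop("`order` must be 0 or 1")
  d <- dim(v$data)
  newdim <- pmax(1L, as.integer(round(d * v$spacing / new_spacing)))
  ratio <- new_spacing / v$spacing
  arr <- resample3d(v$data, as.integer(newdim), ratio, as.integer(order))
  out <- v
  out$data <- arr
  out$spacing <- new_spacing
  if (v$intensity_kind == "mask") out$data <- (arr > 0.5) * 1
  out
}

#' Clip and normalize Hounsfield units to \[0, 1\]
#'
#' Values are clipped to the window `[lo, hi]` and mapped affinely to
#' \[0, 1\]. The default window of -160 to 240 HU brackets soft tissue and
#' contrast-enhanced blood.
#'
#' @param v a `ct_volume` in HU.
#' @param lo,hi window endpoints in HU, `lo < hi`.
#' @return A `ct_volume` with `intensity_kind = "normalized"`.
#' @export
window_normalize <- function(v, lo = -160, hi = 240) {
  if (lo >= hi) stop("window must satisfy lo < hi")
  if (v$intensity_kind != "HU")
    stop("window_normalize expects a volume in HU, got ", v$intensity_kind)
  out <- v
  out$data <- pmin(pmax(v$data, lo), hi)
  out$data <- (out$data - lo) / (hi - lo)
  out$intensity_kind <- "normalized"
  out
}

#' Specify a volume of interest
#'
#' @param center 1-based voxel index triple of the VOI centre.
#' @param target `"aorta"` or `"pulmonary_artery"`; selects the default
#'   shape (128 x 128 x 64 and 96 x 96 x 32 voxels respectively).
#' @param shape optional explicit voxel extent triple, overriding the target
#'   default.
#' @return A `voi_spec` object.
#' @export
voi_spec <- function(center, target = c("aorta", "pulmonary_artery"), shape = NULL) {
  target <- match.arg(target)
  if (is.null(shape))
    shape <- if (target == "aorta") c(128L, 128L, 64L) else c(96L, 96L, 32L)
  structure(list(center = as.integer(round(center)), shape = as.integer(shape),
                 target = target), class = "voi_spec")
}

#' Extract a fixed-size volume of interest
#'
#' Cuts a `spec$shape` crop centred on `spec$center`; voxels falling outside
#' the source are filled with `pad_value`. The placement is recorded in the
#' `"placement"` attribute so masks predicted in VOI space can be pasted back
#' with [paste_voi()].
#'
#' @param v a `ct_volume`.
#' @param spec a [voi_spec()].
#' @param pad_value fill value for out-of-bounds voxels (default 0, the
#'   normalized floor).
#' @return A `ct_volume` of exactly `spec$shape` voxels.
#' @export
extract_voi <- function(v, spec, pad_value = 0) {
  d <- dim(v$data)
  ctr <- spec$center
  if (any(ctr < 1L) || any(ctr > d))
    stop("VOI center (", paste(ctr, collapse = ","),
         ") lies outside the volume of dim (", paste(d, collapse = ","), ")")
  sh <- spec$shape
  start <- ctr - sh %/% 2L  # voxel in source aligned with VOI voxel (1,1,1)
  out <- array(pad_value, dim = sh)
  src_lo <- pmax(start, 1L)
  src_hi <- pmin(start + sh - 1L, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start + 1L
    dst_hi <- src_hi - start + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      v$data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  res <- v
  res$data <- out
  res$origin <- v$origin + (start - 1L) * v$spacing
  attr(res, "placement") <- list(start = start, source_dim = d,
                                 source_origin = v$origin)
  res
}

#' Paste a VOI back into full-volume space
#'
#' Inverse of [extract_voi()]: writes the VOI's in-bounds voxels into a
#' volume of the original grid.
#'
#' @param voi a `ct_volume` produced by [extract_voi()] (or any volume plus an
#'   explicit `placement`).
#' @param into optional `ct_volume` to paste into; defaults to a zero volume
#'   of the source grid.
#' @param placement placement record; defaults to `attr(voi, "placement")`.
#' @return A `ct_volume` on the original grid.
#' @export
paste_voi <- function(voi, into = NULL, placement = attr(voi, "placement")) {
  if (is.null(placement)) stop("no placement record: pass `placement` or use a VOI from extract_voi()")
  d <- placement$source_dim
  if (is.null(into)) {
    into <- voi
    into$data <- array(0, dim = d)
    into$origin <- placement$source_origin
    attr(into, "placement") <- NULL
  }
  sh <- dim(voi$data)
  start <- placement$start
  src_lo <- pmax(start, 1L)
  src_hi <- pmin(start + sh - 1L, d)
  if (all(src_lo <= src_hi)) {
    voi_lo <- src_lo - start + 1L
    voi_hi <- src_hi - start + 1L
    into$data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]] <-
      voi$data[voi_lo[1]:voi_hi[1], voi_lo[2]:voi_hi[2], voi_lo[3]:voi_hi[3]]
  }
  into
}
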