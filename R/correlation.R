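#' Cell template for matched filtering
#'
#' A small 3D subvolume (typically cropped around one isolated cell, or
#' rendered from the synthetic cell model) used as the matched filter in
#' [correlate_volume()]. `center_offset` names the voxel treated as the
#' template center; correlation peaks land where this voxel aligns with a
#' cell center.
#'
#' @param data nonnegative numeric 3D array, dims `(sz, sy, sx)`.
#' @param center_offset integer length-3 `(cx, cy, cz)`, 1-based; defaults
#'   to the geometric middle (lower-middle voxel for even extents).
#' @return a `cell_template` object.
#' @export
cell_template <- function(data, center_offset = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("template `data` must be a 3D array (z, y, x)", call. = FALSE)
  }
  if (min(data) < 0) stop("template intensities must be nonnegative", call. = FALSE)
  size_xyz <- rev(dim(data))
  if (is.null(center_offset)) {
    center_offset <- (size_xyz + 1L) %/% 2L
  }
  center_offset <- as.integer(center_offset)
  stopifnot(length(center_offset) == 3L, all(center_offset >= 1L), all(center_offset <= size_xyz))
  structure(data, center_offset = center_offset, class = c("cell_template", "array"))
}

#' @export
print.cell_template <- function(x, ...) {
  d <- dim(x)
  co <- attr(x, "center_offset")
  cat(sprintf(
    "<cell_template> %d x %d x %d voxels (z, y, x), center offset (%d, %d, %d) (x, y, z)\n",
    d[1], d[2], d[3], co[1], co[2], co[3]
  ))
  invisible(x)
}

#' Crop a cell template out of a volume
#'
#' Crops the box of extents `size` (in `(sx, sy, sz)` voxels) centered at
#' `center`. The box must lie fully inside the volume; no padding is
#' performed. For even extents the extra voxel sits on the lower-index
#' side, mirroring the template center convention.
#'
#' @param volume a [volume3d()].
#' @param center `(x, y, z)` voxel coordinates of the box center (rounded
#'   to the nearest voxel).
#' @param size `(sx, sy, sz)` box extents in voxels.
#' @return a [cell_template()].
#' @export
extract_template <- function(volume, center, size = c(21, 21, 11)) {
  stopifnot(length(center) == 3L, length(size) == 3L, all(size >= 1))
  size <- as.integer(size)
  ctr <- as.integer(round(center))
  shape <- vol_shape_xyz(volume) # (nx, ny, nz)
  co <- (size + 1L) %/% 2L # 1-based center offset within the box
  lo <- ctr - co + 1L
  hi <- lo + size - 1L
  if (any(lo < 1L) || any(hi > shape)) {
    stop("template box crosses the volume boundary; choose an interior cell", call. = FALSE)
  }
  dat <- unclass(volume)[lo[3]:hi[3], lo[2]:hi[2], lo[1]:hi[1], drop = FALSE]
  cell_template(dat, center_offset = co)
}

#' Raw 3D cross-correlation via FFT
#'
#' Computes the plain (unnormalized) cross-correlation
#' `C(p) = sum_k V(p + k - c) T(k)` between a volume `V` and template `T`
#' with center offset `c`, using zero-padded FFTs so the result equals
#' linear (non-circular) spatial correlation cropped to the input shape.
#' No rescaling is applied; see [correlate_volume()] for the full
#' preprocessing step.
#'
#' @param volume 3D array (z, y, x), strictly larger than the template in
#'   every dimension.
#' @param template a [cell_template()] (or 3D array; the geometric middle
#'   is then used as center).
#' @return numeric 3D array, same shape as `volume`.
#' @export
cross_correlate <- function(volume, template) {
  if (!inherits(template, "cell_template")) template <- cell_template(template)
  nv <- dim(volume) # (nz, ny, nx)
  nt <- dim(template)
  if (any(nt >= nv)) {
    stop("template must be strictly smaller than the volume in every dimension",
      call. = FALSE
    )
  }
  # center offset in (z, y, x) order, 0-based
  co_xyz <- attr(template, "center_offset")
  c0 <- rev(co_xyz) - 1L
  # pad to at least nv + nt - 1 to make circular correlation linear
  np <- vapply(nv + nt - 1L, function(n) stats::nextn(n, c(2L, 3L, 5L)), integer(1))
  vp <- array(0, np)
  vp[seq_len(nv[1]), seq_len(nv[2]), seq_len(nv[3])] <- volume
  tp <- array(0, np)
  tp[seq_len(nt[1]), seq_len(nt[2]), seq_len(nt[3])] <- template
  # cross-correlation theorem: P[l] = sum_m V[m + l] T[m] (0-based, mod np)
  p <- Re(stats::fft(stats::fft(vp) * Conj(stats::fft(tp)), inverse = TRUE)) / prod(np)
  # C(x0) = P[(x0 - c0) mod np] per axis, 0-based
  idx <- lapply(1:3, function(d) ((seq_len(nv[d]) - 1L - c0[d]) %% np[d]) + 1L)
  p[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Template-matching preprocessing of one volume
#'
#' Cross-correlates the volume with a cell template so that each cell
#' becomes a smooth correlation blob whose peak coincides with the cell
#' center, then linearly rescales the result to the 8-bit range so the
#' fixed detection thresholds apply. Phase-contrast cells cannot be
#' deconvolved (the optics are non-linear, no linear PSF exists), which is
#' why matched filtering is used instead.
#'
#' @param volume a [volume3d()], typically after [enhance_contrast()].
#' @param template a [cell_template()].
#' @param rescale `"volume"` (default) rescales min-max per volume to
#'   `[0, 255]`; `"range"` uses the fixed `scale_range`, for sequences that
#'   should share one global scale; `"none"` returns raw correlation values.
#' @param scale_range numeric length-2 used when `rescale = "range"`.
#' @return a [volume3d()] with the same shape, spacing and frame index as
#'   the input, carrying attribute `correlated = TRUE`.
#' @export
correlate_volume <- function(volume, template,
                             rescale = c("volume", "range", "none"),
                             scale_range = NULL) {
  rescale <- match.arg(rescale)
  raw <- cross_correlate(unclass(volume), template)
  out <- switch(rescale,
    none = raw,
    volume = {
      rng <- range(raw)
      if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) * 255 else raw * 0
    },
    range = {
      stopifnot(length(scale_range) == 2L, scale_range[2] > scale_range[1])
      pmin(pmax((raw - scale_range[1]) / (scale_range[2] - scale_range[1]) * 255, 0), 255)
    }
  )
  dim(out) <- dim(volume)
  v <- vol_like(out, volume)
  attr(v, "correlated") <- TRUE
  v
}
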