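#' 3D intensity volume
#'
#' A `volume3d` is a numeric 3D array with axis order `(z, y, x)` plus the
#' physical voxel spacing and the frame index of the time point it belongs
#' to. All positions handled by the package are continuous voxel
#' coordinates in `(x, y, z)` order, 1-based (the first voxel center is at
#' `(1, 1, 1)`); physical units enter only through `spacing`, in µm/voxel
#' per axis.
#'
#' @param data numeric 3D array, dimensions `(nz, ny, nx)`.
#' @param spacing numeric length-3, voxel size in µm along `(x, y, z)`.
#'   The default matches a typical low-magnification phase-contrast stack:
#'   0.78 µm in X/Y and 8 µm between Z slices.
#' @param frame nonnegative integer frame index (0-based in time).
#'
#' @return a `volume3d` object.
#' @export
volume3d <- function(data, spacing = c(0.78, 0.78, 8), frame = 0L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array with axis order (z, y, x)", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (dx, dy, dz) in um", call. = FALSE)
  }
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame) || frame < 0L) {
    stop("`frame` must be a single nonnegative integer", call. = FALSE)
  }
  structure(data,
    spacing = spacing, frame = frame,
    class = c("volume3d", "array")
  )
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf(
    "<volume3d> %d x %d x %d voxels (z, y, x), spacing (%.3g, %.3g, %.3g) um (x, y, z), frame %d\n",
    d[1], d[2], d[3], sp[1], sp[2], sp[3], attr(x, "frame")
  ))
  cat(sprintf(
    "  intensity range [%.4g, %.4g]\n",
    min(x), max(x)
  ))
  invisible(x)
}

#' @rdname volume3d
#' @param x object to test.
#' @export
is_volume3d <- function(x) inherits(x, "volume3d")

# Rebuild a volume3d around new data, keeping metadata from `like`.
vol_like <- function(data, like, frame = attr(like, "frame")) {
  volume3d(data, spacing = attr(like, "spacing"), frame = frame)
}

#' Voxel spacing of a volume
#'
#' @param x a `volume3d`.
#' @return numeric length-3 `(dx, dy, dz)` in µm/voxel.
#' @export
vol_spacing <- function(x) attr(x, "spacing")

#' Shape of a volume in (x, y, z) order
#'
#' `dim()` on a `volume3d` returns the array dims `(nz, ny, nx)`; this
#' helper returns the same extents in `(nx, ny, nz)` order, matching how
#' positions and sizes are expressed everywhere else.
#'
#' @param x a `volume3d` or 3D array.
#' @return integer length-3 `(nx, ny, nz)`.
#' @export
vol_shape_xyz <- function(x) rev(dim(x))
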