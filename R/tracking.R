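#' Mean-shift parameters
#'
#' The flat (uniform) kernel is a cube of `kernel_size` voxels per side in
#' index space; iteration stops when the kernel shift falls below
#' `tolerance` voxels. The defaults (side 7, tolerance 0.01) suit cells of
#' about 15 XY pixels diameter moving rarely more than a cell radius per
#' frame; convergence is insensitive to sides between 3 and 9, while
#' oversized kernels risk being attracted by adjacent cells.
#'
#' @param kernel_size odd cube side in voxels, `>= 3`. Default 7.
#' @param tolerance convergence distance in voxels. Default 0.01.
#' @param max_iterations safety cap on iterations. Default 100.
#' @return a `mean_shift_params` list.
#' @export
mean_shift_params <- function(kernel_size = 7, tolerance = 0.01, max_iterations = 100) {
  kernel_size <- as.integer(kernel_size)
  stopifnot(
    length(kernel_size) == 1L, kernel_size >= 3L, kernel_size %% 2L == 1L,
    tolerance > 0, max_iterations >= 1
  )
  structure(
    list(
      kernel_size = kernel_size, tolerance = tolerance,
      max_iterations = as.integer(max_iterations)
    ),
    class = "mean_shift_params"
  )
}

#' Intensity-weighted kernel mean
#'
#' The mean position of the voxels under the flat kernel centered at
#' `center`, weighted by their correlated intensity. The kernel is a cube
#' of side `kernel_size` voxels positioned continuously: a voxel
#' contributes in proportion to the overlap between its unit cell and the
#' kernel extent `[center - k/2, center + k/2]` per axis, so the kernel
#' mean varies continuously with the kernel position and the mean-shift
#' iteration has no spurious grid-locked fixed points. The window is
#' truncated at the volume borders.
#'
#' @param volume correlated volume (array or [volume3d()]).
#' @param center continuous `(x, y, z)` voxel coordinates.
#' @param kernel_size odd cube side in voxels.
#' @return named numeric `(x, y, z)`; if every weight in the window is
#'   zero, `center` is returned unchanged with attribute `degenerate = TRUE`.
#' @export
kernel_mean <- function(volume, center, kernel_size = 7) {
  d <- dim(volume) # (nz, ny, nx)
  stopifnot(length(center) == 3L)
  h <- kernel_size / 2
  axis_window <- function(c0, n) {
    # voxel i overlaps [c0 - h, c0 + h] iff c0 - h - 0.5 < i < c0 + h + 0.5
    i_min <- max(1L, as.integer(floor(c0 - h - 0.5)) + 1L)
    i_max <- min(n, as.integer(ceiling(c0 + h + 0.5)) - 1L)
    if (i_max < i_min) return(list(idx = integer(), w = numeric()))
    idx <- i_min:i_max
    # overlap of [c0 - h, c0 + h] with the voxel cell [i - 0.5, i + 0.5]
    w <- pmin(idx + 0.5, c0 + h) - pmax(idx - 0.5, c0 - h)
    keep <- w > 0
    list(idx = idx[keep], w = w[keep])
  }
  wx <- axis_window(center[1], d[3])
  wy <- axis_window(center[2], d[2])
  wz <- axis_window(center[3], d[1])
  if (!length(wx$idx) || !length(wy$idx) || !length(wz$idx)) {
    out <- as.numeric(center)
    names(out) <- c("x", "y", "z")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  v <- unclass(volume)[wz$idx, wy$idx, wx$idx, drop = FALSE]
  kw <- outer(outer(wz$w, wy$w), wx$w)
  dim(kw) <- dim(v)
  w <- v * kw
  tot <- sum(w)
  if (tot <= 0) {
    out <- as.numeric(center)
    names(out) <- c("x", "y", "z")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- c(
    x = sum(wx$idx * apply(w, 3, sum)) / tot,
    y = sum(wy$idx * apply(w, 2, sum)) / tot,
    z = sum(wz$idx * apply(w, 1, sum)) / tot
  )
  out
}

#' Mean-shift convergence to the nearest intensity peak
#'
#' Iterates [kernel_mean()] from `start` until the shift magnitude drops
#' below `params$tolerance` (or `max_iterations` is reached). In a
#' correlated volume this climbs to the nearest correlation peak, i.e. the
#' nearest cell center.
#'
#' @param volume correlated volume.
#' @param start continuous `(x, y, z)` starting position.
#' @param params a [mean_shift_params()].
#' @return list with `position` (named `(x, y, z)`), `iterations`,
#'   `converged` (FALSE only if the iteration cap was hit) and
#'   `degenerate` (TRUE if the kernel window held zero total intensity).
#' @export
mean_shift <- function(volume, start, params = mean_shift_params()) {
  pos <- as.numeric(start)
  degenerate <- FALSE
  for (it in seq_len(params$max_iterations)) {
    nxt <- kernel_mean(volume, pos, params$kernel_size)
    if (isTRUE(attr(nxt, "degenerate"))) degenerate <- TRUE
    shift <- sqrt(sum((as.numeric(nxt) - pos)^2))
    pos <- as.numeric(nxt)
    if (shift < params$tolerance) {
      names(pos) <- c("x", "y", "z")
      return(list(position = pos, iterations = it, converged = TRUE, degenerate = degenerate))
    }
  }
  names(pos) <- c("x", "y", "z")
  list(
    position = pos, iterations = params$max_iterations,
    converged = FALSE, degenerate = degenerate
  )
}

#' Is a position near the volume boundary?
#'
#' Tracking is stopped when a cell center comes close to a face of the
#' observed volume: within `xy_margin` voxels of an X or Y face, or
#' `z_margin` slices of a Z face (both inclusive).
#'
#' @param position continuous `(x, y, z)` voxel coordinates (1-based).
#' @param shape volume extents `(nx, ny, nz)` (see [vol_shape_xyz()]).
#' @param xy_margin,z_margin margins in voxels/slices; defaults 10 and 5.
#' @return logical.
#' @export
near_boundary <- function(position, shape, xy_margin = 10, z_margin = 5) {
  p <- as.numeric(position)
  shape <- as.numeric(shape)
  dist_face <- pmin(p - 1, shape - p) # 0 at a face center
  dist_face[1] <= xy_margin || dist_face[2] <= xy_margin || dist_face[3] <= z_margin
}
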