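#' Detection parameters for the soft maximum filter
#'
#' Bundles the three parameters of peak detection in a correlated volume:
#' the anisotropic neighborhood over which local maxima are taken (a cell
#' volume, wider in X/Y than in Z to match the voxel anisotropy), the
#' leniency `soft_thresh` with which a voxel counts as "at" its
#' neighborhood maximum, and `noise_thresh`, the minimal correlated
#' intensity of a genuine cell peak.
#'
#' @param neighborhood `(nx, ny, nz)` window extents in voxels (full side
#'   lengths, not radii). Default `c(20, 20, 10)`.
#' @param soft_thresh intensity leniency on the 8-bit scale. Default 5.
#' @param noise_thresh minimal cell intensity on the 8-bit scale. Default 120.
#' @return a `detection_params` list.
#' @export
detection_params <- function(neighborhood = c(20, 20, 10), soft_thresh = 5,
                             noise_thresh = 120) {
  neighborhood <- as.integer(neighborhood)
  stopifnot(
    length(neighborhood) == 3L, all(neighborhood >= 1L),
    length(soft_thresh) == 1L, soft_thresh >= 0,
    length(noise_thresh) == 1L, noise_thresh > 0, noise_thresh <= 255
  )
  structure(
    list(
      neighborhood = neighborhood,
      soft_thresh = soft_thresh, noise_thresh = noise_thresh
    ),
    class = "detection_params"
  )
}

# Running maximum along one array axis with window offsets -lo..hi,
# truncated at the borders (no padding: out-of-volume voxels never compete).
# axis: 1 = z, 2 = y, 3 = x. Extent w splits as lo = floor(w/2),
# hi = w - 1 - lo, biasing even extents toward lower indices.
axis_running_max <- function(a, w, axis) {
  if (w == 1L) return(a)
  n <- dim(a)[axis]
  lo <- w %/% 2L
  hi <- w - 1L - lo
  out <- array(-Inf, dim(a))
  full <- lapply(dim(a), seq_len)
  for (o in seq.int(-lo, hi)) {
    src <- full
    dst <- full
    # out[i] covers in[i + o]
    i <- seq_len(n)
    keep <- i + o >= 1L & i + o <= n
    dst[[axis]] <- i[keep]
    src[[axis]] <- i[keep] + o
    out[dst[[1]], dst[[2]], dst[[3]]] <- pmax(
      out[dst[[1]], dst[[2]], dst[[3]]],
      a[src[[1]], src[[2]], src[[3]]]
    )
  }
  out
}

#' Anisotropic 3D maximum filter
#'
#' Assigns to each voxel the maximum intensity over the box neighborhood
#' of extents `neighborhood` `(nx, ny, nz)` centered on it. Near the
#' volume faces the neighborhood is truncated to the volume (no padding),
#' so genuine maxima at the border are preserved. Even extents place the
#' extra voxel toward lower indices.
#'
#' @param volume a [volume3d()] or 3D array.
#' @param neighborhood `(nx, ny, nz)` extents in voxels.
#' @return array (or `volume3d`) of local maxima, same shape.
#' @export
max_filter <- function(volume, neighborhood = c(20, 20, 10)) {
  neighborhood <- as.integer(neighborhood)
  stopifnot(length(neighborhood) == 3L, all(neighborhood >= 1L))
  a <- unclass(volume)
  # box max is separable: run per axis; (nx, ny, nz) maps to axes (3, 2, 1)
  a <- axis_running_max(a, neighborhood[3], 1L)
  a <- axis_running_max(a, neighborhood[2], 2L)
  a <- axis_running_max(a, neighborhood[1], 3L)
  if (is_volume3d(volume)) vol_like(a, volume) else a
}

#' Soft-maximum mask
#'
#' Marks the voxels whose intensity is within `soft_thresh` of their local
#' neighborhood maximum: `mask(p) = 1` where
#' `maxvol(p) - volume(p) <= soft_thresh`.
#'
#' @param volume correlated volume (array or [volume3d()]).
#' @param maxvol its [max_filter()] output, same shape.
#' @param soft_thresh leniency in intensity units.
#' @return integer 0/1 array of the same shape.
#' @export
soft_max_mask <- function(volume, maxvol, soft_thresh = 5) {
  if (!identical(dim(volume), dim(maxvol))) {
    stop("`volume` and `maxvol` must share shape", call. = FALSE)
  }
  out <- (unclass(maxvol) - unclass(volume) <= soft_thresh) * 1L
  dim(out) <- dim(volume)
  out
}

#' Segment cell peaks in a correlated volume
#'
#' The full soft-maximum detector: local maxima are found with
#' [max_filter()], voxels within `soft_thresh` of their neighborhood
#' maximum are kept ([soft_max_mask()]), the mask is applied to the
#' correlated volume (`softMax`), and thresholding `softMax >= noise_thresh`
#' removes low-intensity background maxima, leaving one foreground blob per
#' distinguishable cell peak (conjoined cells closer than the neighborhood
#' merge into one blob by design).
#'
#' @param volume correlated volume on the 8-bit scale.
#' @param params a [detection_params()].
#' @return integer 0/1 array, same shape as `volume`.
#' @export
segment_volume <- function(volume, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  mx <- max_filter(volume, params$neighborhood)
  mask <- soft_max_mask(volume, mx, params$soft_thresh)
  soft_max <- mask * unclass(volume)
  out <- (soft_max >= params$noise_thresh) * 1L
  dim(out) <- dim(volume)
  out
}

# 26-connected component labeling of a binary volume.
# Foreground voxels become nodes of an adjacency graph (13 half-neighborhood
# offsets, mirrored by undirected edges); igraph finds the components.
# Returns an integer label array (0 = background), labels ordered by the
# smallest linear index in each component.
label_binary_26 <- function(binary) {
  d <- dim(binary)
  fg <- which(binary != 0)
  labels <- array(0L, d)
  if (length(fg) == 0L) {
    return(labels)
  }
  node <- array(0L, d)
  node[fg] <- seq_along(fg)
  coord <- arrayInd(fg, d) # (z, y, x) rows
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[offs[, 1] * 9 + offs[, 2] * 3 + offs[, 3] > 0, , drop = FALSE] # half shell
  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- coord + matrix(offs[i, ], nrow(coord), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    nb_node <- node[nb_lin]
    hit <- nb_node > 0L
    if (!any(hit)) next
    edges[[i]] <- rbind(node[fg[ok]][hit], nb_node[hit])
  }
  edges <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  # stable relabeling: component containing the smallest voxel index first
  first <- tapply(seq_along(fg), comp, min)
  relabel <- integer(length(first))
  relabel[order(first)] <- seq_along(first)
  labels[fg] <- relabel[comp]
  labels
}

#' Label detected objects in a binary volume
#'
#' Connected components under 26-connectivity, so that diagonal-touching
#' peak plateaus (conjoined cells merged by the soft-max window) stay one
#' object.
#'
#' @param binary 0/1 array from [segment_volume()].
#' @param volume optional correlated volume used to report each object's
#'   peak intensity.
#' @return a `cell_detections` object: a tibble with one row per object
#'   (`label`, `x`, `y`, `z` centroid in voxel coordinates, `n_voxels`,
#'   `peak_intensity`), carrying the integer label volume as attribute
#'   `label_volume`.
#' @export
label_objects <- function(binary, volume = NULL) {
  labels <- label_binary_26(binary)
  n_obj <- max(labels)
  if (n_obj == 0L) {
    out <- tibble::tibble(
      label = integer(), x = double(), y = double(), z = double(),
      n_voxels = integer(), peak_intensity = double()
    )
  } else {
    fg <- which(labels != 0L)
    lab <- labels[fg]
    coord <- arrayInd(fg, dim(labels)) # (z, y, x)
    vals <- if (is.null(volume)) rep(NA_real_, length(fg)) else as.numeric(unclass(volume)[fg])
    out <- tibble::tibble(
      label = lab,
      z = coord[, 1], y = coord[, 2], x = coord[, 3],
      v = vals
    ) |>
      dplyr::group_by(.data$label) |>
      dplyr::summarise(
        x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
        n_voxels = dplyr::n(),
        peak_intensity = if (all(is.na(.data$v))) NA_real_ else max(.data$v),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$label)
  }
  structure(out,
    label_volume = labels,
    class = c("cell_detections", class(out))
  )
}

#' Detect all cell peaks in a correlated volume
#'
#' Composition of [segment_volume()] and [label_objects()]: every
#' distinguishable correlation peak (isolated cell or conjoined cells)
#' becomes one detected object with its centroid and peak intensity.
#' Cells whose correlated peak falls below `noise_thresh` are not
#' detected until their signal rises above it.
#'
#' @param volume correlated volume on the 8-bit scale.
#' @param params a [detection_params()].
#' @return a `cell_detections` tibble (see [label_objects()]), sorted by
#'   label.
#' @export
detect_cells <- function(volume, params = detection_params()) {
  label_objects(segment_volume(volume, params), volume)
}
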