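#' Read a multi-page TIFF stack as a 3D volume
#'
#' Page `k` of the TIFF becomes slice `z = k` of the volume. Pages must be
#' single-channel (grayscale) and share width/height. Intensities are
#' returned on the 0-255 scale regardless of on-disk bit depth (16-bit
#' input is scaled by 255/65535).
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param spacing voxel size `(dx, dy, dz)` in µm (see [volume3d()]).
#' @param frame frame index attached to the volume.
#' @return a [volume3d()] of shape `(n_pages, height, width)`.
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, spacing = c(0.78, 0.78, 8), frame = 0L) {
  if (!file.exists(path)) {
    stop(sprintf("TIFF stack not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, convert = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    stop(sprintf("non-grayscale page(s) in %s: expected single-channel TIFF", path),
      call. = FALSE
    )
  }
  shapes <- vapply(pages, dim, integer(2))
  if (ncol(shapes) > 1L && any(shapes[, -1, drop = FALSE] != shapes[, 1])) {
    stop(sprintf("inconsistent page shapes in %s", path), call. = FALSE)
  }
  nz <- length(pages)
  ny <- shapes[1, 1]
  nx <- shapes[2, 1]
  data <- array(0, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) data[k, , ] <- pages[[k]]
  # readTIFF returns [0,1]; bring back to the 8-bit scale and undo the
  # k/255 quantization exactly for 8-bit sources
  data <- data * 255
  if (max(abs(data - round(data))) < 1e-6) data <- round(data)
  volume3d(data, spacing = spacing, frame = frame)
}

#' Write a volume as a multi-page 8-bit TIFF stack
#'
#' Slice `z = k` becomes page `k`. Intensities are expected in `[0, 255]`
#' and are stored as 8-bit samples; integer-valued input round-trips
#' bit-exactly through [read_stack()].
#'
#' @param volume a [volume3d()] with intensities in `[0, 255]`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  stopifnot(is_volume3d(volume) || (is.array(volume) && length(dim(volume)) == 3L))
  if (min(volume) < 0 || max(volume) > 255) {
    stop("volume intensities must lie in [0, 255] before writing", call. = FALSE)
  }
  nz <- dim(volume)[1]
  pages <- lapply(seq_len(nz), function(k) volume[k, , ] / 255)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  if (!isTRUE(ok == nz)) {
    stop(sprintf("failed to write %d pages to %s", nz, path), call. = FALSE)
  }
  invisible(path)
}

#' Read a time-ordered sequence of TIFF stacks
#'
#' Frame order is defined by lexicographic sort of the file names, or by a
#' two-column manifest CSV (`frame_index,filename`) when given.
#'
#' @param dir directory containing one multi-page TIFF per time point.
#' @param manifest optional CSV path with columns `frame_index, filename`
#'   overriding the lexicographic order.
#' @param spacing,frame_interval sequence geometry: voxel spacing in µm and
#'   minutes per frame (default 4).
#' @param pattern filename glob-to-regex used when listing `dir`.
#' @return a list of [volume3d()] with attributes `frame_interval` and
#'   `spacing`; frame indices run 0, 1, 2, ...
#' @export
read_sequence <- function(dir, manifest = NULL, spacing = c(0.78, 0.78, 8),
                          frame_interval = 4, pattern = "\\.tiff?$") {
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("frame_index", "filename") %in% names(man)))
    man <- man[order(man$frame_index), , drop = FALSE]
    files <- file.path(dir, man$filename)
  } else {
    files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  }
  if (length(files) == 0L) stop(sprintf("no TIFF stacks found in %s", dir), call. = FALSE)
  vols <- lapply(seq_along(files), function(i) {
    read_stack(files[i], spacing = spacing, frame = i - 1L)
  })
  d1 <- dim(vols[[1]])
  for (v in vols) {
    if (!identical(dim(v), d1)) stop("volumes in a sequence must share shape", call. = FALSE)
  }
  structure(vols, frame_interval = frame_interval, spacing = spacing)
}

#' Percentile contrast enhancement
#'
#' Boosts image contrast by clipping intensities at two quantiles and
#' linearly rescaling the clipped range to `[0, 255]`. This suppresses
#' the dim collagen/gel background texture while preserving the ordering
#' of intensities inside the kept window, which is all the downstream
#' correlation step needs.
#'
#' @param volume a [volume3d()] (any intensity scale).
#' @param low,high clip quantiles as fractions, `0 <= low < high <= 1`.
#' @return a [volume3d()] with intensities in `[0, 255]`.
#' @export
enhance_contrast <- function(volume, low = 0.01, high = 0.99) {
  stopifnot(length(low) == 1L, length(high) == 1L)
  if (!(low >= 0 && low < high && high <= 1)) {
    stop("need 0 <= low < high <= 1", call. = FALSE)
  }
  q <- stats::quantile(volume, probs = c(low, high), names = FALSE)
  if (q[2] <= q[1]) {
    warning("volume has no contrast in the clip window; returning all zeros")
    return(vol_like(array(0, dim(volume)), volume))
  }
  out <- (pmin(pmax(unclass(volume), q[1]), q[2]) - q[1]) / (q[2] - q[1]) * 255
  dim(out) <- dim(volume)
  vol_like(out, volume)
}
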