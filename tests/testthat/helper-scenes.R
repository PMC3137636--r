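# Shared fixtures, built in code at test time.

# Track a synthetic scene through the standard preprocessing + loop.
run_scene_tracks <- function(scene, config = track_config(), model = cell_model()) {
  template <- make_template(model)
  provider <- function(f) {
    correlate_volume(enhance_contrast(render_frame(scene, f, model)), template)
  }
  track_volumes(provider, scene$n_frames, config)
}

# One rendered + correlated single-cell volume, reused by detection and
# mean-shift tests. The cell sits at integer coordinates (30, 28, 8).
single_cell_corr <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- tibble::tibble(
        cell_id = 1L, frame = 0L, x = 30, y = 28, z = 8, intensity = 1
      )
      scene <- simulate_scene(0, 1, shape = c(16, 60, 60), seed = 1)
      scene$truth <- truth
      scene$background$amplitude <- 0
      vol <- render_frame(scene, 0)
      cache <<- correlate_volume(enhance_contrast(vol), make_template())
    }
    cache
  }
})

# The default 20-cell benchmark is expensive (~3 min), so the tests that
# inspect it share one run.
cached_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_benchmark(seed = 1)
    cache
  }
})

# Naive per-voxel evaluation of the soft-maximum segmentation
# (independent of the separable running-max implementation).
naive_segment <- function(vol, neighborhood, soft_thresh, noise_thresh) {
  d <- dim(vol)
  lo <- neighborhood %/% 2L # (x, y, z)
  hi <- neighborhood - 1L - lo
  out <- array(0L, d)
  for (z in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[3])) {
        zr <- max(1, z - lo[3]):min(d[1], z + hi[3])
        yr <- max(1, y - lo[2]):min(d[2], y + hi[2])
        xr <- max(1, x - lo[1]):min(d[3], x + hi[1])
        mx <- max(vol[zr, yr, xr])
        in_mask <- (mx - vol[z, y, x]) <= soft_thresh
        out[z, y, x] <- as.integer(in_mask && vol[z, y, x] * in_mask >= noise_thresh)
      }
    }
  }
  out
}
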