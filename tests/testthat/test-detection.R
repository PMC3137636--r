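test_that("max filter matches a naive per-voxel neighborhood maximum", {
  set.seed(41)
  vol <- array(sample(0:255, 6 * 12 * 12, replace = TRUE), c(6, 12, 12))
  for (nb in list(c(5, 5, 3), c(3, 3, 3), c(4, 6, 2))) {
    got <- max_filter(vol, nb)
    lo <- nb %/% 2L
    hi <- nb - 1L - lo
    want <- array(0, dim(vol))
    for (z in 1:6) for (y in 1:12) for (x in 1:12) {
      want[z, y, x] <- max(vol[
        max(1, z - lo[3]):min(6, z + hi[3]),
        max(1, y - lo[2]):min(12, y + hi[2]),
        max(1, x - lo[1]):min(12, x + hi[1])
      ])
    }
    expect_identical(got, want)
  }

  # constants are fixed points; a point dilates to its neighborhood box
  cst <- array(7, c(4, 5, 5))
  expect_identical(max_filter(cst, c(3, 3, 3)), cst)
  pt <- array(0, c(7, 7, 7))
  pt[4, 4, 4] <- 9
  dil <- max_filter(pt, c(3, 3, 3))
  expect_equal(sum(dil == 9), 27)
  expect_true(all(dil[3:5, 3:5, 3:5] == 9))
})

test_that("soft-max mask keeps voxels within the leniency of their local max", {
  cst <- array(100, c(3, 4, 4))
  expect_true(all(soft_max_mask(cst, max_filter(cst, c(3, 3, 3)), 0) == 1))

  # ramp along x: with soft_thresh 5 and neighborhood (3,1,1) the mask is
  # exactly where max(left, self, right) - self <= 5
  ramp <- array(rep(seq(0, 250, length.out = 26), each = 1), c(1, 1, 26))
  mx <- max_filter(ramp, c(3, 1, 1))
  mask <- soft_max_mask(ramp, mx, 5)
  want <- array(0L, dim(ramp))
  for (x in 1:26) {
    mxv <- max(ramp[1, 1, max(1, x - 1):min(26, x + 1)])
    want[1, 1, x] <- as.integer(mxv - ramp[1, 1, x] <= 5)
  }
  expect_identical(mask, want)
  expect_error(soft_max_mask(cst, array(0, c(1, 1, 1))), "shape")
})

test_that("segmentation equals the naive soft-maximum oracle exactly", {
  set.seed(42)
  for (rep in 1:6) {
    d <- c(sample(4:8, 1), sample(8:16, 1), sample(8:16, 1))
    vol <- array(sample(0:255, prod(d), replace = TRUE), d)
    nb <- c(sample(c(3, 5, 20), 1), sample(c(3, 5), 1), sample(c(2, 3), 1))
    soft <- sample(c(0, 5, 12), 1)
    noise <- sample(c(80, 120, 200), 1)
    got <- segment_volume(vol, detection_params(nb, soft, noise))
    expect_identical(got, naive_segment(vol, nb, soft, noise))
  }

  # constants sit entirely above or below noise_thresh
  expect_true(all(segment_volume(array(200, c(3, 5, 5))) == 1))
  expect_true(all(segment_volume(array(100, c(3, 5, 5))) == 0))
})

test_that("thresholds act monotonically", {
  set.seed(43)
  vol <- array(sample(0:255, 5 * 10 * 10, replace = TRUE), c(5, 10, 10))
  mx <- max_filter(vol, c(5, 5, 3))
  m1 <- soft_max_mask(vol, mx, 3)
  m2 <- soft_max_mask(vol, mx, 10)
  expect_true(all(m2 >= m1)) # raising soft_thresh never removes mask voxels
  s1 <- segment_volume(vol, detection_params(c(5, 5, 3), 5, 100))
  s2 <- segment_volume(vol, detection_params(c(5, 5, 3), 5, 180))
  expect_true(all(s1 >= s2)) # raising noise_thresh never adds foreground
})

test_that("labeling uses 26-connectivity with centroids at voxel means", {
  empty <- array(0L, c(4, 6, 6))
  expect_identical(nrow(label_objects(empty)), 0L)

  blk <- array(0L, c(9, 9, 9))
  blk[4:6, 4:6, 4:6] <- 1L
  obj <- label_objects(blk)
  expect_identical(nrow(obj), 1L)
  expect_equal(c(obj$x, obj$y, obj$z), c(5, 5, 5))
  expect_identical(obj$n_voxels, 27L)

  # diagonal-touching blocks merge under 26-connectivity (flood-fill oracle:
  # the two blocks share the corner pair (2,2,2)-(3,3,3))
  two <- array(0L, c(6, 6, 6))
  two[1:2, 1:2, 1:2] <- 1L
  two[3:4, 3:4, 3:4] <- 1L
  expect_identical(nrow(label_objects(two)), 1L)
  # ... but not when a gap of one voxel separates them
  apart <- array(0L, c(8, 8, 8))
  apart[1:2, 1:2, 1:2] <- 1L
  apart[4:5, 4:5, 4:5] <- 1L
  expect_identical(nrow(label_objects(apart)), 2L)
})

test_that("two planted blobs above and below threshold segment as designed", {
  # direct blob construction, oracle = naive evaluation
  blob <- function(vol, c_zyx, peak, sigma = 2.5) {
    d <- dim(vol)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      r2 <- (z - c_zyx[1])^2 + (y - c_zyx[2])^2 + (x - c_zyx[3])^2
      vol[z, y, x] <- vol[z, y, x] + peak * exp(-r2 / (2 * sigma^2))
    }
    vol
  }
  vol <- array(50, c(20, 40, 40))
  vol <- blob(vol, c(10, 10, 10), 150) # peaks at 200
  vol <- blob(vol, c(10, 28, 30), 80) # peaks at 130
  params <- detection_params(c(9, 9, 5), 5, 120)
  seg <- segment_volume(vol, params)
  expect_identical(seg, naive_segment(vol, c(9, 9, 5), 5, 120))
  det <- label_objects(seg, vol)
  expect_identical(nrow(det), 2L)
  expect_equal(sort(round(det$peak_intensity)), c(130, 200))

  # a peak below noise_thresh is not detected until its signal rises
  weak <- array(50, c(20, 40, 40))
  weak <- blob(weak, c(10, 20, 20), 60) # peak 110 < 120
  expect_identical(nrow(detect_cells(weak, params)), 0L)
})

test_that("detection finds well-separated rendered cells near ground truth", {
  set.seed(44)
  scene <- simulate_scene(
    n_cells = 10, n_frames = 1, shape = c(20, 140, 140),
    sigma = c(0, 0, 0), seed = 99, min_separation = 30
  )
  cv <- correlate_volume(enhance_contrast(render_frame(scene, 0)), make_template())
  det <- detect_cells(cv)
  expect_identical(nrow(det), 10L)
  truth <- scene$truth
  for (i in seq_len(nrow(truth))) {
    dx <- abs(det$x - truth$x[i])
    dy <- abs(det$y - truth$y[i])
    dz <- abs(det$z - truth$z[i])
    expect_true(any(dx <= 2 & dy <= 2 & dz <= 1))
  }
})

test_that("conjoined cells closer than the neighborhood appear as one object", {
  truth <- dplyr::bind_rows(
    tibble::tibble(cell_id = 1L, frame = 0L, x = 30, y = 30, z = 8, intensity = 1),
    tibble::tibble(cell_id = 2L, frame = 0L, x = 36, y = 30, z = 8, intensity = 0.9)
  )
  scene <- simulate_scene(0, 1, shape = c(16, 70, 70), seed = 1)
  scene$truth <- truth
  scene$background$amplitude <- 0
  cv <- correlate_volume(enhance_contrast(render_frame(scene, 0)), make_template())
  expect_identical(nrow(detect_cells(cv)), 1L)
})
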