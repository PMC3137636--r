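test_that("physical conversion applies anisotropic spacing and frame time", {
  traj <- tibble::tibble(frame = c(0L, 15L), x = c(0, 1), y = 0, z = 0)
  phys <- to_physical(traj, spacing = c(0.78, 0.78, 8), frame_interval = 4)
  expect_equal(diff(phys$x_um), 0.78)
  expect_equal(diff(phys$time_h), 1.0) # 15 frames at 4 min
  trz <- tibble::tibble(frame = c(0L, 1L), x = 0, y = 0, z = c(0, 1))
  expect_equal(diff(to_physical(trz)$z_um), 8)
})

test_that("average speed and MRDO match hand-computed toy paths", {
  # stationary: both zero
  still <- to_physical(tibble::tibble(frame = 0:10, x = 5, y = 5, z = 5))
  expect_equal(average_speed(still), 0)
  expect_equal(as.numeric(mrdo(still)), 0)

  # 3-4-5 displacement over one hour: 5 um/h
  tr <- tibble::tibble(frame = c(0L, 15L), x = c(0, 3 / 0.78), y = c(0, 4 / 0.78), z = 0)
  phys <- to_physical(tr)
  expect_equal(average_speed(phys), 5)
  expect_equal(as.numeric(mrdo(phys)), 5)
  expect_equal(attr(mrdo(phys), "max_displacement_um"), 5)

  # straight line at constant 10 um/h
  line <- to_physical(tibble::tibble(
    frame = seq(0L, 45L, by = 15L), x = (0:3) * 10 / 0.78, y = 0, z = 0
  ))
  expect_equal(average_speed(line), 10)
  expect_equal(as.numeric(mrdo(line)), 10)

  # zig-zag: speed equals hand-summed path length over duration,
  # and out-and-back displacement stays below path length
  zig <- to_physical(tibble::tibble(
    frame = c(0L, 15L, 30L), x = c(0, 5 / 0.78, 0), y = 0, z = 0
  ))
  expect_equal(average_speed(zig), 10 / 2)
  expect_lt(as.numeric(mrdo(zig)), average_speed(zig))

  expect_error(average_speed(still[1, ]))
  expect_error(mrdo(still[1, ]))
})

test_that("speed dominates MRDO on random trajectories, with equality on lines", {
  set.seed(61)
  for (rep in 1:1000) {
    n <- sample(3:12, 1)
    tr <- tibble::tibble(
      frame = seq_len(n) - 1L,
      x = cumsum(rnorm(n)), y = cumsum(rnorm(n)), z = cumsum(rnorm(n, sd = 0.2))
    )
    phys <- to_physical(tr)
    expect_gte(average_speed(phys) - as.numeric(mrdo(phys)), -1e-9)
  }
  # equality for straight constant-velocity paths
  line <- to_physical(tibble::tibble(frame = 0:10, x = (0:10) * 2, y = (0:10), z = 0))
  expect_equal(average_speed(line), as.numeric(mrdo(line)), tolerance = 1e-9)
})

test_that("features are invariant to rigid translation and frame relabeling", {
  set.seed(62)
  tr <- tibble::tibble(
    frame = 0:20, x = cumsum(rnorm(21)), y = cumsum(rnorm(21)), z = cumsum(rnorm(21, sd = 0.1))
  )
  sft <- dplyr::mutate(tr, x = .data$x + 40, y = .data$y - 17, frame = .data$frame + 100L)
  f1 <- c(average_speed(to_physical(tr)), as.numeric(mrdo(to_physical(tr))))
  f2 <- c(average_speed(to_physical(sft)), as.numeric(mrdo(to_physical(sft))))
  expect_equal(f1, f2)
})

test_that("the follow-up filter keeps exactly the trajectories long enough", {
  traj <- dplyr::bind_rows(
    tibble::tibble(tracker_id = 1L, frame = 0:43, x = 0, y = 0, z = 0), # 44 frames
    tibble::tibble(tracker_id = 2L, frame = 0:44, x = 0, y = 0, z = 0), # 45 frames
    tibble::tibble(tracker_id = 3L, frame = 10:80, x = 0, y = 0, z = 0)
  )
  kept <- filter_min_duration(traj, 45)
  expect_equal(sort(unique(kept$tracker_id)), c(2L, 3L))
  expect_identical(nrow(filter_min_duration(traj[0, ], 45)), 0L)
  expect_lte(nrow(filter_min_duration(traj, 45)), nrow(traj))
})

test_that("trajectory features table computes per-trajectory descriptors", {
  traj <- dplyr::bind_rows(
    tibble::tibble(tracker_id = 1L, frame = 0:59, x = (0:59) * 0.5, y = 10, z = 8),
    tibble::tibble(tracker_id = 2L, frame = 0:9, x = 0, y = 0, z = 0) # filtered out
  )
  fx <- trajectory_features(traj, min_frames = 45)
  expect_identical(nrow(fx), 1L)
  expect_equal(fx$n_frames, 60L)
  expect_equal(fx$duration_h, 59 * 4 / 60)
  v <- 0.5 * 0.78 / (4 / 60) # voxels/frame to um/h
  expect_equal(fx$avg_speed_um_h, v)
  expect_equal(fx$mrdo_um_h, v)
  expect_gte(fx$avg_speed_um_h, fx$mrdo_um_h)
})

test_that("the k-sample comparison reproduces the rank statistic", {
  fx <- tibble::tibble(
    condition = rep(c("a", "b", "c"), each = 3),
    avg_speed_um_h = c(1, 2, 3, 101, 102, 103, 201, 202, 203)
  )
  cmp <- compare_conditions(fx)
  # hand-computed Kruskal-Wallis H without ties:
  # ranks 1..9, rank sums 6, 15+... per condition
  ranks <- rank(fx$avg_speed_um_h)
  rs <- tapply(ranks, fx$condition, sum)
  n <- 9
  H <- 12 / (n * (n + 1)) * sum(rs^2 / 3) - 3 * (n + 1)
  expect_equal(cmp$statistic, H)
  expect_equal(cmp$df, 2)
  expect_lt(cmp$p_value, 0.05)

  g <- glance(cmp)
  expect_equal(g$statistic, H)
  td <- tidy(cmp)
  expect_equal(td$n, rep(3L, 3))
  expect_equal(td$median[td$condition == "b"], 102)
})

test_that("identical distributions give a null comparison", {
  fx <- tibble::tibble(
    condition = rep(c("a", "b"), each = 20),
    avg_speed_um_h = rep(seq(1, 20), 2)
  )
  cmp <- compare_conditions(fx)
  expect_lt(cmp$statistic, 0.5)
  expect_gt(cmp$p_value, 0.5)
  # all-identical tied values are handled by tie-corrected ranks
  tied <- tibble::tibble(
    condition = rep(c("a", "b"), each = 5),
    avg_speed_um_h = c(rep(1, 5), 1:5)
  )
  expect_s3_class(compare_conditions(tied), "condition_comparison")
  expect_error(compare_conditions(fx[fx$condition == "a", ]), "2 conditions")
})

test_that("a planted dose-response is detected across conditions", {
  # planted increasing drift speeds with noise, n = 50 per condition
  set.seed(63)
  make_cond <- function(name, v_um_h, n = 50) {
    purrr::map_dfr(seq_len(n), function(i) {
      nf <- 46
      step_vox <- v_um_h * (4 / 60) / 0.78
      tibble::tibble(
        condition = name, tracker_id = i,
        frame = seq_len(nf) - 1L,
        x = cumsum(c(0, rnorm(nf - 1, step_vox, 0.05))),
        y = cumsum(c(0, rnorm(nf - 1, 0, 0.05))),
        z = 8
      )
    })
  }
  trajs <- dplyr::bind_rows(
    make_cond("low", 2), make_cond("mid", 5), make_cond("high", 10)
  )
  fx <- trajs |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ trajectory_features(.x, min_frames = 45)) |>
    dplyr::ungroup()
  cmp <- compare_conditions(fx, "avg_speed_um_h")
  expect_lt(cmp$p_value, 0.001)
  med <- tidy(cmp)
  expect_true(med$median[med$condition == "high"] >
    med$median[med$condition == "low"])
})
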