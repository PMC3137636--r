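# Union-find oracle for grouping by pairwise proximity.
uf_groups <- function(positions, d_xy, d_z) {
  n <- nrow(positions)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j &&
      abs(positions$x[i] - positions$x[j]) <= d_xy &&
      abs(positions$y[i] - positions$y[j]) <= d_xy &&
      abs(positions$z[i] - positions$z[j]) <= d_z) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  gs <- split(positions$id, roots)
  gs <- gs[vapply(gs, length, integer(1)) >= 2L]
  unname(lapply(gs, function(g) sort(as.integer(g))))
}

test_that("collision groups are connected components of the proximity relation", {
  same <- tibble::tibble(id = 1:2, x = c(10, 10), y = c(10, 10), z = c(5, 5))
  expect_equal(find_collisions(same), list(1:2))

  far <- tibble::tibble(id = 1:3, x = c(10, 40, 80), y = 10, z = 5)
  expect_equal(find_collisions(far), list())

  # chain A~B, B~C without A~C forms one group (union-find oracle)
  chain <- tibble::tibble(id = 1:3, x = c(10, 13, 16), y = 10, z = 5)
  got <- find_collisions(chain, d_xy = 3.5, d_z = 2)
  expect_equal(lapply(got, sort), uf_groups(chain, 3.5, 2))
  expect_equal(sort(got[[1]]), 1:3)

  # randomized agreement with the oracle
  set.seed(51)
  for (rep in 1:10) {
    pos <- tibble::tibble(
      id = 1:8, x = runif(8, 0, 25), y = runif(8, 0, 25), z = runif(8, 0, 6)
    )
    got <- find_collisions(pos, 3.5, 2)
    want <- uf_groups(pos, 3.5, 2)
    norm <- function(gs) {
      gs <- lapply(gs, sort)
      gs[order(vapply(gs, min, integer(1)))]
    }
    expect_equal(norm(got), norm(want))
  }
})

test_that("collision resolution stops all unless a unique parasite exists", {
  lt <- function(...) {
    v <- c(...)
    stats::setNames(v, seq_along(v))
  }
  # two established trajectories: both stop
  r <- resolve_collision(c(1L, 2L), lt(50, 60), 5)
  expect_equal(r$resolution, "all_stopped")
  expect_equal(sort(r$stopped), 1:2)
  # unique short-lived tracker: removed as parasite, the other continues
  r <- resolve_collision(c(1L, 2L), lt(3, 40), 5)
  expect_equal(r$resolution, "parasite_removed")
  expect_equal(r$parasite, 1L)
  expect_length(r$stopped, 0)
  # both within the parasite range: ambiguity stops everyone
  r <- resolve_collision(c(1L, 2L), lt(3, 4), 5)
  expect_equal(r$resolution, "all_stopped")
  # boundary case: lifetime exactly parasite_max_life counts as short
  r <- resolve_collision(c(1L, 2L), lt(5, 6), 5)
  expect_equal(r$resolution, "parasite_removed")
  expect_equal(r$parasite, 1L)
})

test_that("association partitions objects by tracker membership", {
  seg <- array(0L, c(6, 20, 20))
  seg[3:4, 4:6, 4:6] <- 1L
  seg[3:4, 14:16, 14:16] <- 1L
  det <- label_objects(seg)
  # one tracker inside the first object
  one <- tibble::tibble(id = 1L, x = 5, y = 5, z = 3)
  a <- associate_trackers(one, det)
  expect_equal(a$tracked, 1L)
  expect_equal(a$untracked, 2L)
  # no trackers: everything untracked (initialization frame)
  none <- tibble::tibble(id = integer(), x = double(), y = double(), z = double())
  a0 <- associate_trackers(none, det)
  expect_length(a0$tracked, 0)
  expect_equal(sort(a0$untracked), 1:2)
  # a tracker between the objects leaves both untracked and is tolerated
  mid <- tibble::tibble(id = 7L, x = 10, y = 10, z = 3)
  am <- associate_trackers(mid, det)
  expect_equal(am$tracker_label$label, 0L)
  expect_equal(sort(am$untracked), 1:2)
})

test_that("spawning places one tracker per untracked object at its centroid", {
  seg <- array(0L, c(6, 20, 20))
  seg[3:4, 4:6, 4:6] <- 1L
  det <- label_objects(seg)
  expect_identical(nrow(spawn_on_untracked(det, integer(), 5L, 3L)), 0L)
  tk <- spawn_on_untracked(det, 1L, 5L, 3L)
  expect_equal(tk$id, 5L)
  expect_equal(c(tk$x, tk$y, tk$z), c(5, 5, 3.5))
  expect_equal(tk$birth_frame, 3L)

  # non-convex object whose centroid is outside: tracker snaps into it
  ushape <- array(0L, c(3, 5, 9))
  ushape[2, 2, 1:9] <- 1L
  ushape[2, 3:4, 1:2] <- 1L
  ushape[2, 3:4, 8:9] <- 1L
  detu <- label_objects(ushape)
  tku <- spawn_on_untracked(detu, 1L, 1L, 0L)
  lab <- attr(detu, "label_volume")
  expect_equal(lab[round(tku$z), round(tku$y), round(tku$x)], 1L)
})

test_that("a single static cell yields one stable trajectory", {
  truth <- tibble::tibble(
    cell_id = 1L, frame = 0:9, x = 30, y = 30, z = 8, intensity = 1
  )
  scene <- simulate_scene(0, 10, shape = c(16, 60, 60), seed = 1)
  scene$truth <- truth
  scene$background$amplitude <- 0
  tracks <- run_scene_tracks(scene)
  expect_identical(nrow(tracks$meta), 1L)
  expect_identical(nrow(tracks$trajectories), 10L)
  expect_true(all(abs(tracks$trajectories$x - 30) <= 1))
  expect_true(all(abs(tracks$trajectories$y - 30) <= 1))
  expect_equal(tracks$meta$end_reason, "sequence_end")
})

test_that("a scripted two-cell crossing produces the four-trajectory timeline", {
  tracks <- run_scene_tracks(scene_crossing())
  meta <- dplyr::arrange(tracks$meta, .data$tracker_id)
  expect_identical(nrow(meta), 4L)
  # A and B track from frame 0 and end together at the collision
  expect_equal(meta$birth_frame[1:2], c(0L, 0L))
  expect_equal(meta$end_reason[1:2], c("collision", "collision"))
  expect_equal(meta$last_frame[1], meta$last_frame[2])
  collision_frame <- meta$last_frame[1] + 1L
  # C spans the conjoined interval, starting at the collision frame
  expect_equal(meta$birth_frame[3], collision_frame)
  # D starts when the cells part, strictly later
  expect_gt(meta$birth_frame[4], meta$birth_frame[3])
  expect_equal(meta$end_reason[3:4], c("sequence_end", "sequence_end"))
  expect_equal(meta$last_frame[3:4], rep(max(tracks$trajectories$frame), 2))
})

test_that("parasite trackers are removed without breaking the long trajectory", {
  tracks <- run_scene_tracks(scene_parasite(secondary_frames = 3))
  meta <- tracks$meta
  expect_identical(nrow(meta), 2L)
  main <- meta[meta$tracker_id == 1L, ]
  para <- meta[meta$tracker_id == 2L, ]
  expect_equal(main$end_reason, "sequence_end")
  expect_equal(main$n_points, 20L) # unbroken
  expect_equal(para$end_reason, "parasite")
  expect_lte(para$n_points, 5L)
})

test_that("two long-lived colliding trackers both stop", {
  tracks <- run_scene_tracks(scene_parasite(secondary_frames = 7))
  meta <- tracks$meta
  both <- meta[meta$tracker_id %in% 1:2, ]
  expect_equal(both$end_reason, c("collision", "collision"))
  expect_equal(both$last_frame[1], both$last_frame[2])
  # the conjoined object is picked up by a fresh tracker
  expect_true(any(meta$birth_frame == both$last_frame[1] + 1L))
})

test_that("division keeps the parent tracker and spawns one for the child", {
  tracks <- run_scene_tracks(scene_division())
  meta <- tracks$meta
  parent <- meta[meta$tracker_id == 1L, ]
  expect_equal(parent$end_reason, "sequence_end")
  expect_equal(parent$n_points, 20L)
  # the departing product eventually holds its own surviving tracker
  survivors <- meta[meta$end_reason == "sequence_end", ]
  expect_identical(nrow(survivors), 2L)
  child <- survivors[survivors$tracker_id != 1L, ]
  expect_gte(child$birth_frame, 4L)
  last <- tracks$trajectories[tracks$trajectories$tracker_id == child$tracker_id, ]
  expect_gt(max(last$x), 40) # it followed the departing cell
})

test_that("trajectory bookkeeping is conserved", {
  tracks <- run_scene_tracks(scene_crossing())
  meta <- tracks$meta
  traj <- tracks$trajectories
  # single ownership: one trajectory per tracker id, consecutive frames
  expect_identical(anyDuplicated(meta$tracker_id), 0L)
  by_id <- split(traj$frame, traj$tracker_id)
  for (f in by_id) expect_equal(f, seq(min(f), max(f)))
  # every non-ongoing trajectory has exactly one end reason
  expect_true(all(meta$end_reason %in%
    c("collision", "boundary", "parasite", "sequence_end")))
  # collision stop counts match the event log
  ev <- tracks$events
  stopped_in_events <- sum(lengths(strsplit(
    ev$tracker_ids[ev$type == "collision_stop"], ";"
  )))
  expect_equal(sum(meta$end_reason == "collision"), stopped_in_events)
})

test_that("tracker count stays constant on an event-free scene", {
  scene <- simulate_scene(
    n_cells = 5, n_frames = 12, shape = c(16, 120, 120),
    sigma = c(0.5, 0.5, 0.1), seed = 7, min_separation = 35
  )
  scene$background$amplitude <- 0 # no texture: no oversegmentation blips
  tracks <- run_scene_tracks(scene)
  expect_identical(nrow(tracks$meta), 5L)
  expect_true(all(tracks$frame_stats$n_active == 5))
  expect_true(all(tracks$frame_stats$n_untracked_after == 0))
})
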