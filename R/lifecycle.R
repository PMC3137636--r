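#' Tracking loop configuration
#'
#' Collects every parameter of the per-frame tracking loop with its
#' default value. An empty call reproduces the reference setup: detection
#' neighborhood 20x20x10 voxels with soft_thresh 5 and noise_thresh 120,
#' flat mean-shift kernel of side 7 with 0.01-voxel stop tolerance,
#' boundary margins of 10 XY voxels and 5 Z slices, collision distances of
#' half a kernel (3.5 voxels) in X/Y and 2 slices in Z, and a parasite
#' lifetime cap of 5 frames.
#'
#' @param detection a [detection_params()].
#' @param mean_shift a [mean_shift_params()].
#' @param xy_margin,z_margin boundary stop margins (voxels / slices).
#' @param collision_d_xy,collision_d_z per-axis proximity thresholds under
#'   which converged trackers count as collided.
#' @param parasite_max_life maximum lifetime, in frames, of a "parasite"
#'   tracker (a short-lived tracker born of a false or duplicated
#'   detection that is removed when it collides with a longer trajectory).
#' @return a `track_config` list.
#' @export
track_config <- function(detection = detection_params(),
                         mean_shift = mean_shift_params(),
                         xy_margin = 10, z_margin = 5,
                         collision_d_xy = 3.5, collision_d_z = 2,
                         parasite_max_life = 5) {
  stopifnot(
    inherits(detection, "detection_params"),
    inherits(mean_shift, "mean_shift_params"),
    xy_margin >= 0, z_margin >= 0,
    collision_d_xy >= 0, collision_d_z >= 0, parasite_max_life >= 0
  )
  structure(
    list(
      detection = detection, mean_shift = mean_shift,
      xy_margin = xy_margin, z_margin = z_margin,
      collision_d_xy = collision_d_xy, collision_d_z = collision_d_z,
      parasite_max_life = parasite_max_life
    ),
    class = "track_config"
  )
}

#' Group trackers that converged to the same location
#'
#' Two converged trackers collide when their positions differ by at most
#' `d_xy` in each of x and y and at most `d_z` in z (Z is scaled
#' separately because of the voxel anisotropy). Collision groups are the
#' connected components of this pairwise proximity relation, so a chain
#' A~B, B~C forms one group even if A and C are farther apart.
#'
#' @param positions tibble/data frame with columns `id`, `x`, `y`, `z` of
#'   converged active trackers.
#' @param d_xy,d_z per-axis proximity thresholds in voxels.
#' @return list of integer id vectors, one per group of size >= 2.
#' @export
find_collisions <- function(positions, d_xy = 3.5, d_z = 2) {
  n <- nrow(positions)
  if (n < 2L) return(list())
  near <- function(v, d) abs(outer(v, v, "-")) <= d
  adj <- near(positions$x, d_xy) & near(positions$y, d_xy) & near(positions$z, d_z)
  diag(adj) <- FALSE
  if (!any(adj)) return(list())
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(positions$id, comp)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  unname(lapply(groups, as.integer))
}

#' Resolve one tracker collision
#'
#' When trackers collide it is in general impossible (even for an expert)
#' to tell which went where, so all colliding trajectories are stopped —
#' unless exactly one member of the group is extremely short-lived
#' (lifetime at most `parasite_max_life` frames). Such a "parasite",
#' typically spawned by a false detection or oversegmentation that
#' immediately converged onto an already-tracked cell, is removed while
#' the longer trajectory continues unaffected. If more than one member is
#' within the parasite range the ambiguity is resolved conservatively:
#' everyone stops.
#'
#' @param group integer ids of the colliding trackers (length >= 2).
#' @param lifetimes named numeric: lifetime in frames (tracked points) per
#'   tracker id.
#' @param parasite_max_life frames; default 5.
#' @return list with `resolution` (`"parasite_removed"` or
#'   `"all_stopped"`), `parasite` (id or `NA`), and `stopped` (ids whose
#'   trajectories end).
#' @export
resolve_collision <- function(group, lifetimes, parasite_max_life = 5) {
  stopifnot(length(group) >= 2L)
  lt <- lifetimes[as.character(group)]
  short <- which(lt <= parasite_max_life)
  if (length(short) == 1L) {
    list(
      resolution = "parasite_removed",
      parasite = as.integer(group[short]),
      stopped = integer()
    )
  } else {
    list(
      resolution = "all_stopped",
      parasite = NA_integer_,
      stopped = as.integer(group)
    )
  }
}

#' Associate converged trackers with detected objects
#'
#' A detected object is tracked iff at least one active tracker's rounded
#' position lies inside its voxel set; every other object is untracked
#' and will receive a new tracker. A tracker sitting in background (its
#' cell's peak may have dipped below `noise_thresh`) is tolerated and
#' stays active.
#'
#' @param positions tibble with `id`, `x`, `y`, `z` of active trackers.
#' @param detections a `cell_detections` from [detect_cells()].
#' @return list with `tracker_label` (tibble `id`, `label`; 0 =
#'   background), `tracked` and `untracked` (integer label vectors).
#' @export
associate_trackers <- function(positions, detections) {
  labels <- attr(detections, "label_volume")
  d <- dim(labels)
  get_label <- function(x, y, z) {
    zi <- as.integer(round(z)); yi <- as.integer(round(y)); xi <- as.integer(round(x))
    if (zi < 1L || zi > d[1] || yi < 1L || yi > d[2] || xi < 1L || xi > d[3]) {
      return(0L)
    }
    labels[zi, yi, xi]
  }
  tl <- if (nrow(positions) == 0L) integer() else {
    mapply(get_label, positions$x, positions$y, positions$z)
  }
  all_labels <- detections$label
  tracked <- sort(unique(tl[tl > 0L]))
  list(
    tracker_label = tibble::tibble(id = positions$id, label = as.integer(tl)),
    tracked = tracked,
    untracked = setdiff(all_labels, tracked)
  )
}

#' Spawn trackers on untracked objects
#'
#' One new active tracker per untracked object, placed at the object's
#' geometric center (centroid). If the rounded centroid falls outside the
#' object's voxel set (possible for strongly non-convex components) the
#' tracker snaps to the nearest member voxel so that every object really
#' does contain its tracker.
#'
#' @param detections a `cell_detections`.
#' @param untracked integer labels to spawn on.
#' @param next_id first id to assign; ids are consecutive and never reused.
#' @param frame birth frame.
#' @return tibble of new trackers (`id`, `x`, `y`, `z`, `birth_frame`,
#'   `state`).
#' @export
spawn_on_untracked <- function(detections, untracked, next_id, frame) {
  if (length(untracked) == 0L) {
    return(tibble::tibble(
      id = integer(), x = double(), y = double(), z = double(),
      birth_frame = integer(), state = character()
    ))
  }
  labels <- attr(detections, "label_volume")
  d <- dim(labels)
  rows <- detections[match(untracked, detections$label), , drop = FALSE]
  pos <- matrix(0, nrow(rows), 3)
  for (i in seq_len(nrow(rows))) {
    p <- c(rows$x[i], rows$y[i], rows$z[i])
    ri <- as.integer(round(c(p[3], p[2], p[1]))) # (z, y, x)
    inside <- all(ri >= 1L) && all(ri <= d) && labels[ri[1], ri[2], ri[3]] == rows$label[i]
    if (!inside) {
      vox <- which(labels == rows$label[i])
      co <- arrayInd(vox, d) # (z, y, x)
      dd <- (co[, 3] - p[1])^2 + (co[, 2] - p[2])^2 + (co[, 1] - p[3])^2
      k <- which.min(dd)
      p <- c(co[k, 3], co[k, 2], co[k, 1])
    }
    pos[i, ] <- p
  }
  tibble::tibble(
    id = seq.int(next_id, length.out = nrow(rows)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    birth_frame = as.integer(frame), state = "active"
  )
}

#' Fresh empty tracking state
#'
#' The state threaded through [advance_frame()]: live trackers, per-tracker
#' trajectories, the event log and the next available tracker id.
#'
#' @return a list state for [advance_frame()].
#' @export
new_track_state <- function() {
  list(
    trackers = tibble::tibble(
      id = integer(), x = double(), y = double(), z = double(),
      birth_frame = integer(), state = character()
    ),
    traj = list(), # per id: matrix (frame, x, y, z)
    events = list(),
    frame_stats = list(),
    next_id = 1L
  )
}

append_point <- function(state, id, frame, x, y, z) {
  key <- as.character(id)
  state$traj[[key]] <- rbind(state$traj[[key]], c(frame, x, y, z))
  state
}

log_event <- function(state, frame, type, ids, detail = "") {
  state$events[[length(state$events) + 1L]] <- tibble::tibble(
    frame = as.integer(frame), type = type,
    tracker_ids = paste(ids, collapse = ";"), detail = detail
  )
  state
}

#' Advance the tracking state by one frame
#'
#' Executes the per-frame loop on a correlated volume: (a) converge every
#' active tracker by mean shift; (b) stop trackers near the volume
#' boundary; (c) detect and resolve tracker collisions (see
#' [resolve_collision()]); (d) detect all cell peaks; (e) associate
#' trackers to objects; (f) spawn a tracker on every untracked object.
#' Converged positions are appended to surviving trajectories;
#' collision-stopped (and parasite) trajectories end at the previous
#' frame's position. A tracker spawned at frame `t` holds the object
#' centroid at `t` and first converges at `t + 1`.
#'
#' @param state tracking state from [new_track_state()] or a previous call.
#' @param corr_volume the correlated volume of the current frame.
#' @param frame current frame index (0-based, consecutive).
#' @param config a [track_config()].
#' @return the updated state.
#' @export
advance_frame <- function(state, corr_volume, frame, config = track_config()) {
  shape <- vol_shape_xyz(corr_volume)
  trk <- state$trackers
  active <- which(trk$state == "active")

  # (a) mean-shift convergence of all active trackers
  for (i in active) {
    res <- mean_shift(
      corr_volume, c(trk$x[i], trk$y[i], trk$z[i]),
      config$mean_shift
    )
    trk$x[i] <- res$position[1]
    trk$y[i] <- res$position[2]
    trk$z[i] <- res$position[3]
    if (res$degenerate) {
      state <- log_event(state, frame, "degenerate_kernel", trk$id[i])
    }
  }

  # (b) boundary stops: the final converged point is kept
  for (i in active) {
    if (near_boundary(
      c(trk$x[i], trk$y[i], trk$z[i]), shape,
      config$xy_margin, config$z_margin
    )) {
      trk$state[i] <- "stopped_boundary"
      state <- append_point(state, trk$id[i], frame, trk$x[i], trk$y[i], trk$z[i])
      state <- log_event(state, frame, "boundary_stop", trk$id[i])
    }
  }

  # (c) collision detection and resolution among still-active trackers
  act <- trk$state == "active"
  groups <- find_collisions(
    trk[act, c("id", "x", "y", "z")],
    config$collision_d_xy, config$collision_d_z
  )
  lifetimes <- vapply(state$traj, nrow, integer(1)) # named by id
  for (g in groups) {
    lt <- stats::setNames(
      lifetimes[as.character(g)] + 1L, # +1: the point being tracked this frame
      as.character(g)
    )
    lt[is.na(lt)] <- 1L
    res <- resolve_collision(g, lt, config$parasite_max_life)
    if (res$resolution == "parasite_removed") {
      i <- match(res$parasite, trk$id)
      trk$state[i] <- "removed_parasite"
      state <- log_event(
        state, frame, "parasite_removed", res$parasite,
        paste("group", paste(g, collapse = ";"))
      )
    } else {
      for (id in res$stopped) {
        trk$state[match(id, trk$id)] <- "stopped_collision"
      }
      state <- log_event(state, frame, "collision_stop", res$stopped)
    }
  }

  # append converged positions of trackers that survived this frame
  for (i in which(trk$state == "active")) {
    state <- append_point(state, trk$id[i], frame, trk$x[i], trk$y[i], trk$z[i])
  }

  # (d) detect all cell peaks
  detections <- detect_cells(corr_volume, config$detection)

  # (e) associate, (f) spawn on untracked objects
  act <- trk$state == "active"
  assoc <- associate_trackers(trk[act, c("id", "x", "y", "z")], detections)
  spawned <- spawn_on_untracked(detections, assoc$untracked, state$next_id, frame)
  if (nrow(spawned) > 0L) {
    trk <- dplyr::bind_rows(trk, spawned)
    for (i in seq_len(nrow(spawned))) {
      state <- append_point(
        state, spawned$id[i], frame,
        spawned$x[i], spawned$y[i], spawned$z[i]
      )
    }
    state <- log_event(state, frame, "spawn", spawned$id)
    state$next_id <- state$next_id + nrow(spawned)
  }

  # invariant bookkeeping: after spawning, every object must hold a tracker
  act <- trk$state == "active"
  post <- associate_trackers(trk[act, c("id", "x", "y", "z")], detections)
  state$frame_stats[[length(state$frame_stats) + 1L]] <- tibble::tibble(
    frame = as.integer(frame),
    n_active = sum(act),
    n_objects = nrow(detections),
    n_untracked_after = length(post$untracked),
    n_spawned = nrow(spawned),
    n_collision_groups = length(groups)
  )

  state$trackers <- trk
  state
}

end_reason_of <- function(state_chr) {
  switch(state_chr,
    active = "sequence_end",
    stopped_collision = "collision",
    stopped_boundary = "boundary",
    removed_parasite = "parasite",
    stopped_end = "sequence_end",
    state_chr
  )
}

#' Track a sequence of correlated volumes
#'
#' Runs [advance_frame()] over `n_frames` correlated volumes supplied by
#' `frame_provider` and assembles the resulting trajectories.
#'
#' @param frame_provider function(frame_index) returning the correlated
#'   [volume3d()] of that 0-based frame.
#' @param n_frames number of frames to process.
#' @param config a [track_config()].
#' @return a `cell_tracks` object: list with `trajectories` (tibble
#'   `tracker_id`, `frame`, `x`, `y`, `z`), `meta` (tibble `tracker_id`,
#'   `birth_frame`, `last_frame`, `n_points`, `end_reason`), `events`,
#'   `frame_stats`, and the `config` used.
#' @export
track_volumes <- function(frame_provider, n_frames, config = track_config()) {
  state <- new_track_state()
  for (f in seq_len(n_frames) - 1L) {
    state <- advance_frame(state, frame_provider(f), f, config)
  }
  ids <- as.integer(names(state$traj))
  traj <- purrr::map_dfr(names(state$traj), function(key) {
    m <- state$traj[[key]]
    tibble::tibble(
      tracker_id = as.integer(key), frame = as.integer(m[, 1]),
      x = m[, 2], y = m[, 3], z = m[, 4]
    )
  }) |>
    dplyr::arrange(.data$tracker_id, .data$frame)
  trk <- state$trackers
  meta <- tibble::tibble(
    tracker_id = trk$id,
    birth_frame = trk$birth_frame,
    last_frame = vapply(
      as.character(trk$id),
      function(k) as.integer(max(state$traj[[k]][, 1])), integer(1),
      USE.NAMES = FALSE
    ),
    n_points = vapply(
      as.character(trk$id),
      function(k) nrow(state$traj[[k]]), integer(1),
      USE.NAMES = FALSE
    ),
    end_reason = vapply(trk$state, end_reason_of, character(1), USE.NAMES = FALSE)
  ) |>
    dplyr::arrange(.data$tracker_id)
  structure(
    list(
      trajectories = traj,
      meta = meta,
      events = if (length(state$events)) dplyr::bind_rows(state$events) else
        tibble::tibble(
          frame = integer(), type = character(),
          tracker_ids = character(), detail = character()
        ),
      frame_stats = dplyr::bind_rows(state$frame_stats),
      config = config
    ),
    class = "cell_tracks"
  )
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf(
    "<cell_tracks> %d trajectories over %d frames\n",
    nrow(x$meta), nrow(x$frame_stats)
  ))
  print(table(x$meta$end_reason))
  invisible(x)
}

#' Tidy a `cell_tracks` object into one row per tracked point
#'
#' @param x a `cell_tracks`.
#' @param ... unused.
#' @return tibble `tracker_id, frame, x, y, z` joined with the
#'   trajectory's `birth_frame`, `last_frame`, `end_reason`.
#' @export
tidy.cell_tracks <- function(x, ...) {
  dplyr::left_join(x$trajectories, x$meta, by = "tracker_id")
}

#' One-row summary of a tracking run
#'
#' @param x a `cell_tracks`.
#' @param ... unused.
#' @return tibble with trajectory counts by end reason and the peak number
#'   of simultaneously active trackers.
#' @export
glance.cell_tracks <- function(x, ...) {
  tibble::tibble(
    n_trajectories = nrow(x$meta),
    n_frames = nrow(x$frame_stats),
    n_collision = sum(x$meta$end_reason == "collision"),
    n_parasite = sum(x$meta$end_reason == "parasite"),
    n_boundary = sum(x$meta$end_reason == "boundary"),
    max_active = max(x$frame_stats$n_active),
    max_untracked_after_spawn = max(x$frame_stats$n_untracked_after)
  )
}
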