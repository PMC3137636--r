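#' Synthetic phase-contrast cell appearance model
#'
#' In low-magnification phase-contrast stacks a cell appears as a small
#' bright disk in its focal slice with off-focus interference rings that
#' grow with defocus — a pair of cones squashed into each other. The model
#' reproduces that geometry as an additive pattern: a Gaussian-profile
#' bright disk at the focal slice and, at slice offset `dz`, a ring of
#' radius `ring_slope * |dz|` whose amplitude decays linearly to zero at
#' `z_extent / 2 + 1` slices.
#'
#' @param focal_radius XY radius of the focal disk in voxels (default 7.5,
#'   i.e. a 15-pixel cell diameter).
#' @param z_extent number of Z slices the pattern covers (default 12).
#' @param peak_intensity 8-bit intensity at the focal center (default 200).
#' @param halo_amplitude peak intensity of the off-focus rings (default 60).
#' @param ring_slope ring radius growth in voxels per slice of defocus.
#' @param halo_sign +1 for bright rings (default; the pipeline works on
#'   contrast-boosted nonnegative data), -1 to stress-test dark lobes.
#' @return a `cell_model` list.
#' @export
cell_model <- function(focal_radius = 7.5, z_extent = 12, peak_intensity = 200,
                       halo_amplitude = 60, ring_slope = 1.3, halo_sign = 1) {
  stopifnot(
    focal_radius > 0, z_extent >= 1, peak_intensity > 0, peak_intensity <= 255,
    halo_amplitude >= 0, ring_slope >= 0, halo_sign %in% c(-1, 1)
  )
  structure(
    list(
      focal_radius = focal_radius, z_extent = z_extent,
      peak_intensity = peak_intensity, halo_amplitude = halo_amplitude,
      ring_slope = ring_slope, halo_sign = halo_sign,
      # edge of the focal disk at ~3 sigma: a 15-px diameter cell reads
      # as a bright core of sigma ~2.5 voxels
      radial_sigma = focal_radius / 3
    ),
    class = "cell_model"
  )
}

# XY patch radius that contains the pattern support.
model_patch_radius <- function(model) {
  ceiling(model$ring_slope * model$z_extent / 2 + 3 * model$radial_sigma)
}

#' Render one cell into a canvas
#'
#' Adds the double-cone phase-contrast pattern of `model` at the
#' continuous position `center`; overlapping cells add up, and the caller
#' clips to `[0, 255]` once per frame.
#'
#' @param canvas 3D array (z, y, x) to draw into.
#' @param model a [cell_model()].
#' @param center continuous `(x, y, z)` voxel coordinates inside the canvas.
#' @param scale per-cell intensity factor (cell peaks vary in practice,
#'   which is what the detection `noise_thresh` accounts for).
#' @return the canvas with the pattern added.
#' @export
render_cell <- function(canvas, model, center, scale = 1) {
  d <- dim(canvas)
  cx <- center[1]; cy <- center[2]; cz <- center[3]
  ze2 <- model$z_extent / 2
  rr <- model_patch_radius(model)
  xs <- max(1L, floor(cx - rr)):min(d[3], ceiling(cx + rr))
  ys <- max(1L, floor(cy - rr)):min(d[2], ceiling(cy + rr))
  zs <- max(1L, floor(cz - ze2)):min(d[1], ceiling(cz + ze2))
  if (length(xs) == 0L || length(ys) == 0L || length(zs) == 0L) return(canvas)
  r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+")) # (y, x)
  s2 <- 2 * model$radial_sigma^2
  for (z in zs) {
    dz <- abs(z - cz)
    if (dz > ze2) next
    decay <- 1 - dz / (ze2 + 1)
    r0 <- model$ring_slope * dz
    amp <- if (dz < 0.5) model$peak_intensity * decay else
      model$halo_sign * model$halo_amplitude * decay
    canvas[z, ys, xs] <- canvas[z, ys, xs] + scale * amp * exp(-(r - r0)^2 / s2)
  }
  canvas
}

# Run a seeded expression without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv()) else
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
  })
  set.seed(seed)
  expr
}

# Separable running mean (box smoothing) with truncated borders.
axis_running_sum <- function(a, w, axis) {
  if (w == 1L) return(list(sum = a, count = array(1, dim(a))))
  n <- dim(a)[axis]
  lo <- w %/% 2L
  hi <- w - 1L - lo
  s <- array(0, dim(a))
  cnt <- array(0, dim(a))
  full <- lapply(dim(a), seq_len)
  ones <- array(1, dim(a))
  for (o in seq.int(-lo, hi)) {
    i <- seq_len(n)
    keep <- i + o >= 1L & i + o <= n
    dst <- full; src <- full
    dst[[axis]] <- i[keep]
    src[[axis]] <- i[keep] + o
    s[dst[[1]], dst[[2]], dst[[3]]] <- s[dst[[1]], dst[[2]], dst[[3]]] +
      a[src[[1]], src[[2]], src[[3]]]
    cnt[dst[[1]], dst[[2]], dst[[3]]] <- cnt[dst[[1]], dst[[2]], dst[[3]]] +
      ones[src[[1]], src[[2]], src[[3]]]
  }
  list(sum = s, count = cnt)
}

box_smooth <- function(a, window = c(5, 5, 3)) {
  # window in (x, y, z) extents
  num <- a
  den <- array(1, dim(a))
  for (ax in 1:3) {
    w <- as.integer(window[4 - ax]) # axis 1 = z -> window[3]
    r <- axis_running_sum(num, w, ax)
    num <- r$sum
    d <- axis_running_sum(den, w, ax)
    den <- d$sum
  }
  num / den
}

# Band-limited background texture standing in for collagen-fiber artifacts:
# smoothed white noise, standardized, scaled to `amplitude` and shifted so
# the background mean sits at `amplitude` (nonnegative after clipping).
background_texture <- function(dim_zyx, amplitude, seed, window = c(5, 5, 3)) {
  if (amplitude <= 0) return(array(0, dim_zyx))
  with_local_seed(seed, {
    w <- array(stats::rnorm(prod(dim_zyx)), dim_zyx)
    sm <- box_smooth(w, window)
    sm <- (sm - mean(sm)) / stats::sd(sm)
    pmax(amplitude + amplitude * sm, 0)
  })
}

reflect_into <- function(v, lo, hi) {
  # reflect a coordinate into [lo, hi]
  if (hi <= lo) return(rep(lo, length(v)))
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  v <- ifelse(v > span, 2 * span - v, v)
  v + lo
}

#' Simulate a ground-truthed synthetic scene
#'
#' Generates seeded ground-truth cell paths inside a volume: Gaussian
#' random walks (optionally drifting) reflected at an inset box that keeps
#' freely wandering cells out of the tracking stop margin, plus scripted
#' motion events: `crossing` (two cells steered onto straight
#' pass-through paths that intersect at a given frame), `division` (a
#' child path splits off a parent with linearly growing offset), `entry`
#' (a new cell appears at the inset edge and moves inward) and `exit`
#' (a cell is steered out through the nearest face).
#'
#' @param n_cells number of base cells (>= 0).
#' @param n_frames number of time points.
#' @param shape volume dims `(nz, ny, nx)`.
#' @param spacing voxel size `(dx, dy, dz)` µm.
#' @param frame_interval minutes per frame.
#' @param sigma random-walk step s.d. per axis `(x, y, z)` in voxels/frame.
#' @param drift deterministic drift per axis in voxels/frame.
#' @param events list of event specs, e.g.
#'   `list(type = "crossing", cells = c(1, 2), frame = 35, speed = 1.2)`,
#'   `list(type = "division", cell = 5, frame = 40)`,
#'   `list(type = "entry", frame = 25)`,
#'   `list(type = "exit", cell = 7, frame = 60)`.
#' @param seed RNG seed; identical seeds give identical scenes.
#' @param inset_xy,inset_z reflection inset in voxels from the X/Y and Z
#'   faces (defaults 12 and 7: stop margin + 2).
#' @param init_positions optional matrix (n_cells x 3) of `(x, y, z)`
#'   starting positions; otherwise sampled with `min_separation`.
#' @param min_separation minimal XY distance between sampled starts.
#' @return a `synthetic_scene`: list with `truth` (tibble `cell_id`,
#'   `frame`, `x`, `y`, `z`), `shape`, `spacing`, `frame_interval`,
#'   `n_frames`, `events`, `seed`, `background` (amplitude settable via
#'   [render_frame()]).
#' @export
simulate_scene <- function(n_cells, n_frames, shape = c(24, 160, 160),
                           spacing = c(0.78, 0.78, 8), frame_interval = 4,
                           sigma = c(0.8, 0.8, 0.15), drift = c(0, 0, 0),
                           events = list(), seed = 1,
                           inset_xy = 12, inset_z = 7,
                           init_positions = NULL, min_separation = 20) {
  stopifnot(n_cells >= 0, n_frames >= 1, length(shape) == 3L)
  ext <- rev(shape) # (nx, ny, nz)
  lo <- c(inset_xy + 1, inset_xy + 1, inset_z + 1)
  hi <- c(ext[1] - inset_xy, ext[2] - inset_xy, ext[3] - inset_z)
  if (any(hi <= lo)) stop("shape too small for the requested insets", call. = FALSE)

  paths <- list() # per cell: matrix n_frames x 3, NA when absent
  intens <- numeric() # per-cell peak intensity factor
  with_local_seed(seed, {
    intens <- stats::runif(n_cells, 0.85, 1)
    # starting positions
    if (is.null(init_positions) && n_cells > 0L) {
      init_positions <- matrix(NA_real_, n_cells, 3)
      for (i in seq_len(n_cells)) {
        for (try in 1:500) {
          p <- c(
            stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]),
            stats::runif(1, lo[3], hi[3])
          )
          if (i == 1L) break
          dmin <- min(sqrt((init_positions[seq_len(i - 1), 1] - p[1])^2 +
            (init_positions[seq_len(i - 1), 2] - p[2])^2), na.rm = TRUE)
          if (dmin >= min_separation) break
        }
        init_positions[i, ] <- p
      }
    }
    # base reflected random walks
    for (i in seq_len(n_cells)) {
      steps <- cbind(
        stats::rnorm(n_frames - 1, drift[1], sigma[1]),
        stats::rnorm(n_frames - 1, drift[2], sigma[2]),
        stats::rnorm(n_frames - 1, drift[3], sigma[3])
      )
      p <- apply(rbind(init_positions[i, , drop = FALSE], steps), 2, cumsum)
      p <- matrix(p, ncol = 3)
      for (ax in 1:3) p[, ax] <- reflect_into(p[, ax], lo[ax], hi[ax])
      paths[[i]] <- p
    }
    next_cell <- n_cells + 1L
    frames0 <- seq_len(n_frames) - 1L
    jitter_path <- function(m, s = 0.15) {
      m + cbind(
        stats::rnorm(nrow(m), 0, s), stats::rnorm(nrow(m), 0, s),
        stats::rnorm(nrow(m), 0, s * 0.4)
      )
    }
    for (ev in events) {
      type <- ev$type
      if (type == "crossing") {
        ij <- ev$cells
        k <- ev$frame
        speed <- if (is.null(ev$speed)) 1.2 else ev$speed
        pass <- if (is.null(ev$pass_distance)) 2 else ev$pass_distance
        m <- (init_positions[ij[1], ] + init_positions[ij[2], ]) / 2
        m[3] <- mean(c(lo[3], hi[3]))
        u <- init_positions[ij[1], 1:2] - m[1:2]
        nu <- sqrt(sum(u^2))
        u <- if (nu < 1e-6) c(1, 0) else u / nu
        perp <- c(-u[2], u[1])
        for (w in 1:2) {
          sgn <- if (w == 1L) 1 else -1
          ctr <- m
          ctr[1:2] <- m[1:2] + sgn * perp * pass / 2
          dirv <- c(sgn * u * speed, 0)
          p <- matrix(rep(ctr, each = n_frames), ncol = 3) -
            outer(frames0 - k, dirv)
          for (ax in 1:3) p[, ax] <- reflect_into(p[, ax], lo[ax], hi[ax])
          paths[[ij[w]]] <- jitter_path(p)
        }
      } else if (type == "division") {
        k <- ev$frame
        parent <- ev$cell
        if (parent > length(paths) || is.null(paths[[parent]])) {
          stop("division event references a nonexistent cell", call. = FALSE)
        }
        sep <- if (is.null(ev$separation)) 14 else ev$separation
        ramp_n <- if (is.null(ev$ramp_frames)) 10 else ev$ramp_frames
        th <- stats::runif(1, 0, 2 * pi)
        u <- c(cos(th), sin(th), 0)
        child <- matrix(NA_real_, n_frames, 3)
        for (t in (k + 1):n_frames) { # 1-based row = frame t-1
          off <- min(1 + (t - 1 - k) / ramp_n * (sep - 1), sep)
          child[t, ] <- paths[[parent]][t, ] + u * off
        }
        # after the ramp, continue as an independent walk
        t_free <- k + 1 + ramp_n
        if (t_free < n_frames) {
          nfree <- n_frames - t_free
          steps <- cbind(
            stats::rnorm(nfree, 0, sigma[1]), stats::rnorm(nfree, 0, sigma[2]),
            stats::rnorm(nfree, 0, sigma[3])
          )
          child[(t_free + 1):n_frames, ] <-
            matrix(rep(child[t_free, ], each = nfree), ncol = 3) +
            apply(steps, 2, cumsum)
        }
        for (ax in 1:3) {
          ok <- !is.na(child[, ax])
          child[ok, ax] <- reflect_into(child[ok, ax], lo[ax], hi[ax])
        }
        paths[[next_cell]] <- child
        intens[next_cell] <- intens[parent] * 0.93 # daughters start dimmer
        next_cell <- next_cell + 1L
      } else if (type == "entry") {
        k <- ev$frame
        speed <- if (is.null(ev$speed)) 1.0 else ev$speed
        p0 <- c(lo[1], stats::runif(1, lo[2], hi[2]), stats::runif(1, lo[3], hi[3]))
        child <- matrix(NA_real_, n_frames, 3)
        nlive <- n_frames - k
        steps <- cbind(
          stats::rnorm(nlive - 1, speed, sigma[1]),
          stats::rnorm(nlive - 1, 0, sigma[2]),
          stats::rnorm(nlive - 1, 0, sigma[3])
        )
        p <- apply(rbind(matrix(p0, 1), steps), 2, cumsum)
        p <- matrix(p, ncol = 3)
        for (ax in 1:3) p[, ax] <- reflect_into(p[, ax], lo[ax], hi[ax])
        child[(k + 1):n_frames, ] <- p
        paths[[next_cell]] <- child
        intens[next_cell] <- stats::runif(1, 0.85, 1)
        next_cell <- next_cell + 1L
      } else if (type == "exit") {
        k <- ev$frame
        i <- ev$cell
        if (i > length(paths) || is.null(paths[[i]])) {
          stop("exit event references a nonexistent cell", call. = FALSE)
        }
        speed <- if (is.null(ev$speed)) 1.0 else ev$speed
        p <- paths[[i]]
        pk <- p[k + 1, ]
        # head for the nearest X face and keep going until outside
        dir_x <- if (pk[1] < ext[1] / 2) -1 else 1
        for (t in (k + 2):n_frames) {
          step <- c(dir_x * speed, 0, 0) +
            stats::rnorm(3, 0, c(sigma[1], sigma[2], sigma[3]) * 0.5)
          p[t, ] <- p[t - 1, ] + step
        }
        out_frames <- which(p[, 1] < 1 | p[, 1] > ext[1])
        if (length(out_frames)) p[out_frames[1]:n_frames, ] <- NA_real_
        paths[[i]] <- p
      } else {
        stop(sprintf("unknown event type: %s", type), call. = FALSE)
      }
    }
  })

  empty_truth <- tibble::tibble(
    cell_id = integer(), frame = integer(),
    x = double(), y = double(), z = double(), intensity = double()
  )
  truth <- purrr::map_dfr(seq_along(paths), function(i) {
    p <- paths[[i]]
    ok <- !is.na(p[, 1])
    tibble::tibble(
      cell_id = i, frame = which(ok) - 1L,
      x = p[ok, 1], y = p[ok, 2], z = p[ok, 3],
      intensity = intens[i]
    )
  })
  if (nrow(truth) == 0L) truth <- empty_truth
  structure(
    list(
      truth = truth, shape = as.integer(shape), spacing = spacing,
      frame_interval = frame_interval, n_frames = as.integer(n_frames),
      events = events, seed = as.integer(seed),
      background = list(amplitude = 12, window = c(3, 3, 1))
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d cells, %d frames, volume %d x %d x %d (z, y, x), seed %d\n",
    length(unique(x$truth$cell_id)), x$n_frames,
    x$shape[1], x$shape[2], x$shape[3], x$seed
  ))
  invisible(x)
}

# Per-frame noise seed derived from the scene seed; kept below 2^31.
frame_seed <- function(scene_seed, frame) {
  as.integer((as.numeric(scene_seed) * 131071 + frame * 7919 + 17) %% 2147483587)
}

#' Render one frame of a synthetic scene
#'
#' Draws every cell present at `frame` at its ground-truth position,
#' adds seeded background texture, clips to `[0, 255]`.
#'
#' @param scene a [simulate_scene()] output.
#' @param frame 0-based frame index.
#' @param model a [cell_model()].
#' @return a [volume3d()].
#' @export
render_frame <- function(scene, frame, model = cell_model()) {
  canvas <- background_texture(
    scene$shape, scene$background$amplitude,
    frame_seed(scene$seed, frame), scene$background$window
  )
  present <- scene$truth[scene$truth$frame == frame, , drop = FALSE]
  sc <- if ("intensity" %in% names(present)) present$intensity else rep(1, nrow(present))
  for (i in seq_len(nrow(present))) {
    canvas <- render_cell(
      canvas, model, c(present$x[i], present$y[i], present$z[i]),
      scale = sc[i]
    )
  }
  canvas <- pmin(pmax(canvas, 0), 255)
  dim(canvas) <- scene$shape
  volume3d(canvas, spacing = scene$spacing, frame = frame)
}

#' Render all frames of a scene
#'
#' @param scene a [simulate_scene()] output.
#' @param model a [cell_model()].
#' @return list of [volume3d()] with `frame_interval`/`spacing` attributes,
#'   as from [read_sequence()].
#' @export
render_sequence <- function(scene, model = cell_model()) {
  vols <- lapply(seq_len(scene$n_frames) - 1L, function(f) render_frame(scene, f, model))
  structure(vols, frame_interval = scene$frame_interval, spacing = scene$spacing)
}

#' Synthesize a cell template from the appearance model
#'
#' Renders one cell on a zero background and crops the central box — the
#' synthetic counterpart of manually cropping a template around an
#' isolated cell.
#'
#' @param model a [cell_model()].
#' @param size template extents `(sx, sy, sz)` in voxels.
#' @return a [cell_template()].
#' @export
make_template <- function(model = cell_model(), size = c(21, 21, 11)) {
  rr <- model_patch_radius(model)
  nxy <- 2L * rr + max(size[1:2]) + 3L
  nz <- as.integer(model$z_extent + size[3] + 3L)
  # odd canvas extents put the rendered cell exactly on a voxel center,
  # so the template peak sits exactly at center_offset
  if (nxy %% 2L == 0L) nxy <- nxy + 1L
  if (nz %% 2L == 0L) nz <- nz + 1L
  canvas <- array(0, c(nz, nxy, nxy))
  ctr <- c((nxy + 1) / 2, (nxy + 1) / 2, (nz + 1) / 2)
  canvas <- render_cell(canvas, model, ctr)
  vol <- volume3d(pmin(canvas, 255))
  extract_template(vol, ctr, size)
}

#' Score trajectories against the ground truth of a scene
#'
#' Frame by frame, a trajectory point matches a ground-truth cell when it
#' lies within `match_dist` per axis (`d_xy` in x and y, `d_z` in z).
#' Recall is the fraction of truth points covered by at least one
#' trajectory point, precision the fraction of trajectory points lying
#' within range of some truth point. Each trajectory also carries a
#' matched identity, assigned with hysteresis: the previous identity is
#' kept as long as that cell remains within the match distance, and only
#' when it leaves (while another cell occupies the neighborhood) does the
#' identity change — so transient proximity of two cells (conjoined
#' tracking) does not register as an error, while a tracker that really
#' drifts from one cell to another does. The id-switch fraction is the
#' share of trajectories whose matched identity changes at least once.
#'
#' @param tracks a `cell_tracks` from [track_volumes()].
#' @param scene the [simulate_scene()] ground truth.
#' @param match_dist `(d_xy, d_z)` in voxels; default `c(10, 3)`.
#' @return list with `recall`, `precision`, `id_switch_fraction`,
#'   `n_truth_points`, `n_track_points`, `n_trajectories`, and
#'   `switched_ids` (tracker ids that switched identity).
#' @export
score_against_truth <- function(tracks, scene, match_dist = c(10, 3)) {
  d_xy <- match_dist[1]
  d_z <- match_dist[2]
  traj <- tracks$trajectories
  truth <- scene$truth
  truth_matched <- logical(nrow(truth))
  traj_matched <- logical(nrow(traj))
  truth_by_frame <- split(seq_len(nrow(truth)), truth$frame)

  candidates <- function(j) {
    ti <- truth_by_frame[[as.character(traj$frame[j])]]
    if (is.null(ti)) return(integer())
    dx <- abs(truth$x[ti] - traj$x[j])
    dy <- abs(truth$y[ti] - traj$y[j])
    dz <- abs(truth$z[ti] - traj$z[j])
    ok <- dx <= d_xy & dy <= d_xy & dz <= d_z
    ti[ok][order((dx^2 + dy^2 + dz^2)[ok])]
  }

  ids <- unique(traj$tracker_id)
  switched <- logical(length(ids))
  for (q in seq_along(ids)) {
    rows <- which(traj$tracker_id == ids[q])
    rows <- rows[order(traj$frame[rows])]
    current <- NA_integer_
    for (j in rows) {
      cand <- candidates(j)
      if (length(cand) == 0L) next
      traj_matched[j] <- TRUE
      truth_matched[cand] <- TRUE
      cand_ids <- truth$cell_id[cand]
      if (is.na(current)) {
        current <- cand_ids[1]
      } else if (!(current %in% cand_ids)) {
        switched[q] <- TRUE
        current <- cand_ids[1]
      }
    }
  }
  list(
    recall = mean(truth_matched),
    precision = mean(traj_matched),
    id_switch_fraction = if (length(ids)) mean(switched) else 0,
    n_truth_points = nrow(truth),
    n_track_points = nrow(traj),
    n_trajectories = length(ids),
    switched_ids = ids[switched]
  )
}
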