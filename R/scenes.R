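#' Scripted two-cell crossing scene
#'
#' Two cells on deterministic head-on paths that pass through each other
#' mid-sequence: the canonical tracker-collision scenario. Run through the
#' tracking loop it should produce exactly four trajectories — the two
#' original trackers end at the collision, one tracker follows the
#' conjoined pair, and a fourth starts when the cells part.
#'
#' @param n_frames sequence length (default 21; the paths meet mid-sequence).
#' @param shape volume dims `(nz, ny, nx)`.
#' @param speed approach speed in voxels/frame.
#' @return a `synthetic_scene` with zero background noise (deterministic).
#' @export
scene_crossing <- function(n_frames = 21, shape = c(16, 100, 100), speed = 2) {
  frames <- seq_len(n_frames) - 1L
  meet <- (n_frames - 1) / 2
  x_mid <- 40
  x1 <- x_mid - speed * meet + speed * frames
  x2 <- x_mid + speed * meet - speed * frames
  # unequal brightness and a small lateral offset: two real cells are
  # never identical, and the asymmetry lets the conjoined tracker follow
  # the brighter peak deterministically through the crossing
  truth <- dplyr::bind_rows(
    tibble::tibble(cell_id = 1L, frame = frames, x = x1, y = 40, z = 8, intensity = 1),
    tibble::tibble(cell_id = 2L, frame = frames, x = x2, y = 43, z = 8, intensity = 0.75)
  )
  scripted_scene(truth, shape, n_frames)
}

#' Scripted parasite scene
#'
#' One stationary cell plus a transient secondary peak (e.g. a body
#' extension of an elongated cell detected as a second object) that
#' appears at an offset, persists for a few frames, then retracts onto
#' the cell body so the two trackers collide. With a secondary lifetime
#' within the parasite range its tracker is removed and the main
#' trajectory continues unbroken; with a longer lifetime both trajectories
#' stop.
#'
#' @param secondary_frames number of frames the secondary peak stays at
#'   its offset before retracting (tracker lifetime at collision is
#'   `secondary_frames + 1`).
#' @param n_frames sequence length.
#' @param shape volume dims `(nz, ny, nx)`.
#' @param offset XY offset of the secondary peak in voxels.
#' @return a `synthetic_scene` with zero background noise.
#' @export
scene_parasite <- function(secondary_frames = 3, n_frames = 20,
                           shape = c(16, 64, 64), offset = 14) {
  frames <- seq_len(n_frames) - 1L
  appear <- 5L
  retract <- appear + secondary_frames # first frame back on the cell body
  main <- tibble::tibble(
    cell_id = 1L, frame = frames, x = 32, y = 32, z = 8, intensity = 1
  )
  sec_frames <- appear:retract
  sec <- tibble::tibble(
    cell_id = 2L, frame = sec_frames,
    x = ifelse(sec_frames < retract, 32 + offset, 32.5),
    y = 32, z = 8, intensity = 0.9
  )
  scripted_scene(dplyr::bind_rows(main, sec), shape, n_frames)
}

#' Scripted cell-division scene
#'
#' A stationary parent whose child separates at a constant rate from a
#' given frame: the parent keeps its tracker, the child receives a new
#' one once detected as a separate object.
#'
#' @param division_frame 0-based frame of the split.
#' @param n_frames sequence length.
#' @param shape volume dims `(nz, ny, nx)`.
#' @param rate child separation speed in voxels/frame.
#' @return a `synthetic_scene` with zero background noise.
#' @export
scene_division <- function(division_frame = 4, n_frames = 20,
                           shape = c(16, 72, 72), rate = 1.5) {
  frames <- seq_len(n_frames) - 1L
  parent <- tibble::tibble(
    cell_id = 1L, frame = frames, x = 30, y = 36, z = 8, intensity = 1
  )
  child_frames <- frames[frames >= division_frame]
  child <- tibble::tibble(
    cell_id = 2L, frame = child_frames,
    x = 30 + 1 + rate * (child_frames - division_frame),
    y = 36, z = 8, intensity = 0.9
  )
  scripted_scene(dplyr::bind_rows(parent, child), shape, n_frames)
}

# Wrap a hand-written truth table as a synthetic_scene (no noise, seed 0).
scripted_scene <- function(truth, shape, n_frames,
                           spacing = c(0.78, 0.78, 8), frame_interval = 4) {
  structure(
    list(
      truth = truth, shape = as.integer(shape), spacing = spacing,
      frame_interval = frame_interval, n_frames = as.integer(n_frames),
      events = list(), seed = 0L,
      background = list(amplitude = 0, window = c(3, 3, 1))
    ),
    class = "synthetic_scene"
  )
}

#' Default ground-truthed tracking benchmark scene
#'
#' The standard test bed for the whole pipeline: 20 cells random-walking
#' in a 160 x 160 x 24 voxel volume over 100 frames, with two scripted
#' cell crossings (frames 35 and 65), two cell entries (frames 25 and 55)
#' and one division (frame 40). Initial positions are laid out so that
#' freely wandering cells start well separated and clear of the crossing
#' corridors; everything else is drawn from the seeded motion model.
#'
#' @param seed scene seed.
#' @param background_amplitude background texture level (8-bit units).
#' @return a `synthetic_scene`.
#' @export
benchmark_scene <- function(seed = 1, background_amplitude = 12) {
  init <- rbind(
    c(30, 50, 12), # crossing pair 1 (paths overridden by the event)
    c(94, 50, 12),
    c(110, 30, 12), # crossing pair 2
    c(110, 126, 12),
    c(45, 122, 12), # division parent
    c(25, 85, 10), c(55, 85, 12), c(85, 85, 14), c(135, 85, 12),
    c(25, 108, 14), c(70, 110, 10), c(135, 110, 12),
    c(25, 140, 12), c(55, 138, 10), c(85, 138, 12), c(135, 138, 14),
    c(20, 25, 12), c(45, 25, 10), c(70, 25, 14), c(95, 20, 12)
  )
  scene <- simulate_scene(
    n_cells = 20, n_frames = 100, shape = c(24, 160, 160),
    sigma = c(0.8, 0.8, 0.15),
    events = list(
      list(type = "crossing", cells = c(1, 2), frame = 35, speed = 1.2),
      list(type = "crossing", cells = c(3, 4), frame = 65, speed = 0.75),
      list(type = "division", cell = 5, frame = 40),
      list(type = "entry", frame = 25),
      list(type = "entry", frame = 55)
    ),
    seed = seed, init_positions = init
  )
  scene$background$amplitude <- background_amplitude
  scene
}
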