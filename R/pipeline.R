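#' Default pipeline configuration
#'
#' Every tunable parameter of the end-to-end pipeline with its reference
#' default, as a plain nested list that can be serialized to / merged
#' from YAML. An empty configuration file therefore reproduces the
#' reference setup exactly.
#'
#' @return a named list.
#' @export
default_config <- function() {
  list(
    spacing = c(0.78, 0.78, 8), # um per voxel (x, y, z)
    frame_interval = 4, # minutes per frame
    contrast = list(low = 0.01, high = 0.99),
    template = list(
      source = "synthetic", # or "crop"
      size = c(21, 21, 11), # (sx, sy, sz) voxels
      center = NULL # (x, y, z), for source = "crop"
    ),
    detection = list(
      neighborhood = c(20, 20, 10),
      soft_thresh = 5,
      noise_thresh = 120
    ),
    mean_shift = list(kernel_size = 7, tolerance = 0.01, max_iterations = 100),
    boundary = list(xy_margin = 10, z_margin = 5),
    collision = list(d_xy = 3.5, d_z = 2),
    parasite_max_life = 5,
    min_frames = 45,
    rescale = "volume",
    cache_dir = NULL,
    seed = 1
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()], so a partial
#' (or empty) file yields a complete configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  utils::modifyList(cfg, user)
}

config_to_track_config <- function(cfg) {
  track_config(
    detection = detection_params(
      neighborhood = cfg$detection$neighborhood,
      soft_thresh = cfg$detection$soft_thresh,
      noise_thresh = cfg$detection$noise_thresh
    ),
    mean_shift = mean_shift_params(
      kernel_size = cfg$mean_shift$kernel_size,
      tolerance = cfg$mean_shift$tolerance,
      max_iterations = cfg$mean_shift$max_iterations
    ),
    xy_margin = cfg$boundary$xy_margin,
    z_margin = cfg$boundary$z_margin,
    collision_d_xy = cfg$collision$d_xy,
    collision_d_z = cfg$collision$d_z,
    parasite_max_life = cfg$parasite_max_life
  )
}

resolve_template <- function(cfg, first_volume = NULL, model = cell_model()) {
  if (identical(cfg$template$source, "crop")) {
    if (is.null(first_volume) || is.null(cfg$template$center)) {
      stop("template source 'crop' needs an input volume and template$center",
        call. = FALSE
      )
    }
    extract_template(first_volume, cfg$template$center, cfg$template$size)
  } else {
    make_template(model, cfg$template$size)
  }
}

# One preprocessed (contrast-boosted, correlated) frame.
preprocess_frame <- function(volume, template, cfg) {
  v <- enhance_contrast(volume, cfg$contrast$low, cfg$contrast$high)
  cv <- correlate_volume(v, template, rescale = cfg$rescale)
  if (!is.null(cfg$cache_dir)) {
    dir.create(cfg$cache_dir, showWarnings = FALSE, recursive = TRUE)
    write_stack(
      round(cv),
      file.path(cfg$cache_dir, sprintf("corr_%04d.tif", attr(volume, "frame")))
    )
  }
  cv
}

#' Run the full tracking pipeline
#'
#' Preprocesses every frame (percentile contrast boost, template-matching
#' correlation), runs the per-frame tracking loop, and computes migration
#' features on trajectories passing the minimum follow-up filter. Input
#' may be a directory of multi-page TIFF stacks (one per time point,
#' lexicographic frame order), a list of volumes from [read_sequence()] /
#' [render_sequence()], or a `synthetic_scene` (frames are then rendered
#' on the fly).
#'
#' @param input directory path, volume list, or [simulate_scene()] output.
#' @param config a configuration list (see [default_config()]).
#' @param output_dir if not `NULL`, CSV/JSON artifacts are written there:
#'   `trajectories.csv`, `trajectory_meta.csv`, `features.csv`,
#'   `events.csv`, `frame_stats.csv`, `run_report.json`.
#' @param model the [cell_model()] used for synthetic templates/rendering.
#' @return a `pipeline_result` list: `tracks` (a `cell_tracks`),
#'   `features` tibble, `template`, and the resolved `config`.
#' @export
run_pipeline <- function(input, config = default_config(), output_dir = NULL,
                         model = cell_model()) {
  cfg <- utils::modifyList(default_config(), config)
  if (inherits(input, "synthetic_scene")) {
    n_frames <- input$n_frames
    cfg$spacing <- input$spacing
    cfg$frame_interval <- input$frame_interval
    raw_frame <- function(f) render_frame(input, f, model)
  } else if (is.character(input)) {
    seq_vols <- read_sequence(input,
      spacing = cfg$spacing,
      frame_interval = cfg$frame_interval
    )
    n_frames <- length(seq_vols)
    raw_frame <- function(f) seq_vols[[f + 1L]]
  } else if (is.list(input)) {
    n_frames <- length(input)
    raw_frame <- function(f) input[[f + 1L]]
  } else {
    stop("unsupported input type", call. = FALSE)
  }
  template <- resolve_template(cfg, raw_frame(0L), model)
  provider <- function(f) preprocess_frame(raw_frame(f), template, cfg)
  tracks <- track_volumes(provider, n_frames, config_to_track_config(cfg))
  features <- trajectory_features(
    tracks,
    spacing = cfg$spacing,
    frame_interval = cfg$frame_interval, min_frames = cfg$min_frames
  )
  result <- structure(
    list(tracks = tracks, features = features, template = template, config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$tracks)
  cat(sprintf(
    "%d trajectories passed the %d-frame follow-up filter\n",
    nrow(x$features), x$config$min_frames
  ))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Trajectories are written in both voxel and physical coordinates; the
#' run report embeds the fully resolved configuration so a run can be
#' reproduced from its own output.
#'
#' @param result a `pipeline_result`.
#' @param output_dir destination directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  sp <- cfg$spacing
  traj <- result$tracks$trajectories |>
    dplyr::mutate(
      x_um = .data$x * sp[1], y_um = .data$y * sp[2], z_um = .data$z * sp[3]
    )
  utils::write.csv(traj, file.path(output_dir, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(result$tracks$meta, file.path(output_dir, "trajectory_meta.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$features, file.path(output_dir, "features.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$tracks$events, file.path(output_dir, "events.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$tracks$frame_stats, file.path(output_dir, "frame_stats.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(config = cfg, n_trajectories = nrow(result$tracks$meta)),
    file.path(output_dir, "run_report.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  invisible(output_dir)
}

#' Run the ground-truthed synthetic benchmark
#'
#' Simulates (or takes) a scene, renders and tracks it, and scores the
#' trajectories against the ground truth: recall, precision and the
#' fraction of trajectories with an identity switch.
#'
#' @param scene a `synthetic_scene`; default [benchmark_scene()] with
#'   `seed`.
#' @param config pipeline configuration overrides.
#' @param seed scene seed used when `scene` is `NULL`.
#' @param match_dist `(d_xy, d_z)` scoring distance in voxels.
#' @param output_dir optional artifact directory; adds `benchmark.json`
#'   with the metrics.
#' @param model the [cell_model()].
#' @return a `benchmark_result` list: `metrics`, `result`
#'   (the `pipeline_result`) and `scene`.
#' @export
run_benchmark <- function(scene = NULL, config = default_config(), seed = 1,
                          match_dist = c(10, 3), output_dir = NULL,
                          model = cell_model()) {
  if (is.null(scene)) scene <- benchmark_scene(seed)
  result <- run_pipeline(scene, config, output_dir = output_dir, model = model)
  metrics <- score_against_truth(result$tracks, scene, match_dist)
  if (!is.null(output_dir)) {
    jsonlite::write_json(
      metrics[c(
        "recall", "precision", "id_switch_fraction",
        "n_truth_points", "n_track_points", "n_trajectories"
      )],
      file.path(output_dir, "benchmark.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  structure(
    list(metrics = metrics, result = result, scene = scene),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<benchmark_result> recall %.3f, precision %.3f, id-switch fraction %.3f (%d trajectories)\n",
    m$recall, m$precision, m$id_switch_fraction, m$n_trajectories
  ))
  invisible(x)
}
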