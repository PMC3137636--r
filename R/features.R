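#' Convert a trajectory to physical units
#'
#' Scales voxel positions per axis by the spacing (µm) and frames by the
#' frame interval, yielding time in hours.
#'
#' @param trajectory tibble/data frame with columns `frame`, `x`, `y`, `z`
#'   in voxel units (one tracker).
#' @param spacing `(dx, dy, dz)` µm per voxel.
#' @param frame_interval minutes per frame (default 4).
#' @return tibble with `time_h`, `x_um`, `y_um`, `z_um` added.
#' @export
to_physical <- function(trajectory, spacing = c(0.78, 0.78, 8), frame_interval = 4) {
  stopifnot(nrow(trajectory) >= 1L, all(c("frame", "x", "y", "z") %in% names(trajectory)))
  dplyr::mutate(
    tibble::as_tibble(trajectory),
    time_h = .data$frame * frame_interval / 60,
    x_um = .data$x * spacing[1],
    y_um = .data$y * spacing[2],
    z_um = .data$z * spacing[3]
  )
}

path_steps_um <- function(phys) {
  dx <- diff(phys$x_um)
  dy <- diff(phys$y_um)
  dz <- diff(phys$z_um)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Average cell speed (µm/h)
#'
#' Total path length (sum of Euclidean inter-frame displacements in µm)
#' divided by the elapsed time in hours. Duration normalization makes
#' trajectories of different lengths comparable.
#'
#' @param phys a physical trajectory from [to_physical()], >= 2 points.
#' @return speed in µm/h.
#' @export
average_speed <- function(phys) {
  if (nrow(phys) < 2L) stop("average speed needs at least 2 points", call. = FALSE)
  dt <- max(phys$time_h) - min(phys$time_h)
  sum(path_steps_um(phys)) / dt
}

#' Maximum relative distance from origin, duration-normalized (µm/h)
#'
#' The maximum Euclidean distance (µm) reached from the trajectory's first
#' point, divided by the elapsed time in hours. A displacement-based
#' migration rate: cells that wander without net motion score low even if
#' their average speed is high.
#'
#' @param phys a physical trajectory from [to_physical()], >= 2 points.
#' @return rate in µm/h. The unnormalized maximum displacement is attached
#'   as attribute `max_displacement_um`.
#' @export
mrdo <- function(phys) {
  if (nrow(phys) < 2L) stop("MRDO needs at least 2 points", call. = FALSE)
  dt <- max(phys$time_h) - min(phys$time_h)
  disp <- sqrt((phys$x_um - phys$x_um[1])^2 +
    (phys$y_um - phys$y_um[1])^2 +
    (phys$z_um - phys$z_um[1])^2)
  out <- max(disp) / dt
  attr(out, "max_displacement_um") <- max(disp)
  out
}

#' Drop trajectories with too short a follow-up
#'
#' Duration-normalized features are noisy and outlier-prone on short
#' follow-ups, so trajectories with fewer than `min_frames` tracked points
#' are excluded from the statistical analysis (default 45 frames = 3 h at
#' 4 min/frame).
#'
#' @param trajectories tibble with `tracker_id` and `frame` columns
#'   (e.g. `tracks$trajectories` or [tidy.cell_tracks()] output).
#' @param min_frames minimal number of tracked points, >= 2.
#' @return the subset of rows belonging to trajectories with
#'   `>= min_frames` points.
#' @export
filter_min_duration <- function(trajectories, min_frames = 45) {
  stopifnot(min_frames >= 2)
  dplyr::group_by(trajectories, .data$tracker_id) |>
    dplyr::filter(dplyr::n() >= min_frames) |>
    dplyr::ungroup()
}

#' Migration features for every trajectory
#'
#' Applies the minimum-duration filter then computes, per trajectory, its
#' duration in hours, average speed, duration-normalized MRDO and raw
#' maximum displacement, all in physical units.
#'
#' @param tracks a `cell_tracks` object or a trajectories tibble
#'   (`tracker_id`, `frame`, `x`, `y`, `z`).
#' @param spacing `(dx, dy, dz)` µm per voxel.
#' @param frame_interval minutes per frame.
#' @param min_frames minimal follow-up in frames (default 45); see
#'   [filter_min_duration()].
#' @return tibble with one row per kept trajectory: `tracker_id`,
#'   `n_frames`, `duration_h`, `avg_speed_um_h`, `mrdo_um_h`,
#'   `max_displacement_um`.
#' @export
trajectory_features <- function(tracks, spacing = c(0.78, 0.78, 8),
                                frame_interval = 4, min_frames = 45) {
  traj <- if (inherits(tracks, "cell_tracks")) tracks$trajectories else tracks
  traj <- filter_min_duration(traj, min_frames)
  if (nrow(traj) == 0L) {
    return(tibble::tibble(
      tracker_id = integer(), n_frames = integer(), duration_h = double(),
      avg_speed_um_h = double(), mrdo_um_h = double(),
      max_displacement_um = double()
    ))
  }
  traj |>
    dplyr::group_by(.data$tracker_id) |>
    dplyr::group_modify(function(df, key) {
      phys <- to_physical(df, spacing, frame_interval)
      m <- mrdo(phys)
      tibble::tibble(
        n_frames = nrow(df),
        duration_h = max(phys$time_h) - min(phys$time_h),
        avg_speed_um_h = average_speed(phys),
        mrdo_um_h = as.numeric(m),
        max_displacement_um = attr(m, "max_displacement_um")
      )
    }) |>
    dplyr::ungroup()
}

#' Compare a migration feature across experimental conditions
#'
#' Rank-based k-sample (Kruskal-Wallis) test of a feature's distribution
#' across conditions, with tie-corrected ranks. Feature distributions
#' characterize cell populations; a significant omnibus test indicates a
#' condition effect (e.g. a dose-response) without assuming normality.
#'
#' @param features tibble with a `condition` column and the feature
#'   column, e.g. stacked [trajectory_features()] outputs.
#' @param feature name of the feature column (default `"avg_speed_um_h"`).
#' @return a `condition_comparison` object with the H `statistic`,
#'   degrees of freedom `df`, `p_value`, and a per-condition summary
#'   (n, median, IQR).
#' @export
compare_conditions <- function(features, feature = "avg_speed_um_h") {
  stopifnot("condition" %in% names(features), feature %in% names(features))
  cond <- factor(features$condition)
  if (nlevels(cond) < 2L) stop("need at least 2 conditions", call. = FALSE)
  v <- features[[feature]]
  kt <- stats::kruskal.test(v, cond)
  per_cond <- tibble::tibble(condition = cond, value = v) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      iqr_low = stats::quantile(.data$value, 0.25, names = FALSE),
      iqr_high = stats::quantile(.data$value, 0.75, names = FALSE),
      .groups = "drop"
    )
  structure(
    list(
      feature = feature,
      statistic = unname(kt$statistic),
      df = unname(kt$parameter),
      p_value = kt$p.value,
      conditions = per_cond
    ),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "<condition_comparison> %s: Kruskal-Wallis H = %.4g, df = %d, p = %.3g\n",
    x$feature, x$statistic, x$df, x$p_value
  ))
  print(x$conditions)
  invisible(x)
}

#' @export
tidy.condition_comparison <- function(x, ...) x$conditions

#' @export
glance.condition_comparison <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, statistic = x$statistic,
    df = x$df, p_value = x$p_value
  )
}

#' Distribution plot for a condition comparison
#'
#' Box-and-jitter plot of the compared feature per condition, the usual
#' presentation of per-population migration feature distributions.
#'
#' @param object a `condition_comparison`... except that plotting needs
#'   the raw values, so pass the same `features` tibble.
#' @param features the tibble given to [compare_conditions()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.condition_comparison <- function(object, features, ...) {
  ggplot2::ggplot(
    features,
    ggplot2::aes(
      x = factor(.data$condition),
      y = .data[[object$feature]]
    )
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "condition", y = object$feature,
      subtitle = sprintf(
        "Kruskal-Wallis H = %.3g, p = %.2g",
        object$statistic, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}
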