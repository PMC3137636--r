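#' Plot cell trajectories in the XY plane
#'
#' One path per tracker, colored by id, over the volume footprint — the
#' usual way to eyeball a tracking run.
#'
#' @param object a `cell_tracks`.
#' @param min_frames hide trajectories shorter than this many points
#'   (default 2 shows everything with an actual path).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cell_tracks <- function(object, min_frames = 2, ...) {
  traj <- filter_min_duration(object$trajectories, max(2, min_frames))
  ggplot2::ggplot(
    traj,
    ggplot2::aes(.data$x, .data$y,
      group = .data$tracker_id,
      color = factor(.data$tracker_id)
    )
  ) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_point(
      data = traj |>
        dplyr::group_by(.data$tracker_id) |>
        dplyr::slice_min(.data$frame, n = 1) |>
        dplyr::ungroup(),
      size = 1
    ) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (voxels)", y = "y (voxels)", color = "tracker") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Active-trajectory count over time
#'
#' Number of simultaneously active trackers per frame, with detected
#' object counts — reproduces the usual "active trajectories across the
#' sequence" diagnostic curve.
#'
#' @param tracks a `cell_tracks`.
#' @return a ggplot object.
#' @export
plot_active_trajectories <- function(tracks) {
  fs <- tracks$frame_stats |>
    tidyr::pivot_longer(c("n_active", "n_objects"),
      names_to = "series", values_to = "count"
    )
  ggplot2::ggplot(fs, ggplot2::aes(.data$frame, .data$count, color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(
      values = c(n_active = "#1b6ca8", n_objects = "#c44536"),
      labels = c(n_active = "active trackers", n_objects = "detected objects")
    ) +
    ggplot2::labs(x = "frame", y = "count", color = NULL) +
    ggplot2::theme_minimal()
}
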