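#' Plot fly trajectories in the arena
#'
#' @param tracks A `fly_tracks` tibble.
#' @param geometry An [arena_geometry()] used to draw the wall.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, geometry = arena_geometry()) {
  wall <- tibble::tibble(angle = seq(0, 2 * pi, length.out = 361))
  wall$x <- geometry$radius * cos(wall$angle)
  wall$y <- geometry$radius * sin(wall$angle)
  ggplot2::ggplot(tibble::as_tibble(tracks),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$fly_id,
                               color = .data$fly_id)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_path(data = wall,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, color = "grey30") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' Plot a preference-index time course
#'
#' @param pi_timecourse Output of [preference_index()].
#' @return A ggplot object.
#' @export
plot_preference <- function(pi_timecourse) {
  ggplot2::ggplot(pi_timecourse,
                  ggplot2::aes(x = .data$t, y = .data$pi)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60",
                        linetype = "dashed") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "time (s)", y = "preference index") +
    ggplot2::theme_minimal()
}

#' Plot a z-scored screen matrix
#'
#' Heat map of line-by-parameter z-scores, the screen's overview figure.
#'
#' @param screen Output of [zscore_screen()].
#' @return A ggplot object.
#' @export
plot_screen <- function(screen) {
  ggplot2::ggplot(screen,
                  ggplot2::aes(x = .data$parameter, y = .data$line_id,
                               fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a stimulus-locked metric time course
#'
#' Averages a kinematic metric across flies per frame and overlays the LED
#' epochs — the standard way to look at, e.g., upwind orientation around
#' the stimulus.
#'
#' @param frame_metrics Output of [track_kinematics()].
#' @param schedule An `arena_schedule` (its `led_on` epochs are shaded).
#' @param metric Name of the metric column (default `"cos_upwind"`).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(frame_metrics, schedule,
                            metric = "cos_upwind") {
  mean_tc <- frame_metrics |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(value = mean(.data[[metric]], na.rm = TRUE),
                     .groups = "drop")
  led <- schedule_epochs(schedule, "led_on")
  ggplot2::ggplot(mean_tc, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_rect(data = led,
                       ggplot2::aes(xmin = .data$t_start,
                                    xmax = .data$t_end,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "mistyrose") +
    ggplot2::geom_line(color = "grey20", linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = metric) +
    ggplot2::theme_minimal()
}
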