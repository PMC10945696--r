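#' Per-frame kinematic features
#'
#' Computes, for every (fly, frame), the per-frame metrics used throughout
#' the arena assay: heading, walking `speed` (mm/s), absolute angular change
#' `dtheta_abs` (radians/frame), signed angular change `dtheta`, cosine of
#' upwind orientation `cos_upwind` (upwind is radially outward because air
#' is drawn out at the arena center), distance from the center `dist_center`
#' (mm), and the trailing cumulative turning `cum_turn` over
#' `window_frames` inter-frame changes.
#'
#' Metrics that involve frame-to-frame differences are computed only over
#' consecutive-frame pairs; at tracking gaps (and at each fly's first frame)
#' they are `NA`. The cumulative-turning window is likewise `NA` wherever it
#' would span a gap.
#'
#' @param tracks A `fly_tracks` tibble in arena-centered mm.
#' @param geometry An [arena_geometry()] (used for the center-distance and
#'   upwind metrics; tracks are already centered, so only the radius and
#'   center-hole conventions matter here).
#' @param min_step Displacement threshold (mm) below which the
#'   displacement-derived heading is held at its previous value rather than
#'   recomputed from jitter (default 0.1 mm).
#' @param window_frames Number of inter-frame changes summed in `cum_turn`
#'   (default 5, i.e. about 167 ms at 30 fps).
#' @param heading_from `"auto"` uses the tracker-supplied `heading` column
#'   when present, otherwise the frame-to-frame displacement direction;
#'   `"orientation"` and `"displacement"` force one source.
#' @param signed_turning If `TRUE`, `cum_turn` sums signed angular changes
#'   instead of absolute ones (net rotation rather than total turning).
#' @param center_hole_mm Radius (mm) around the suction hole inside which
#'   the radial direction, hence `cos_upwind`, is undefined (default 0.5).
#' @return A tibble with columns `fly_id`, `frame`, `t`, `x`, `y`,
#'   `heading`, `speed`, `dtheta`, `dtheta_abs`, `cos_upwind`,
#'   `dist_center`, `cum_turn`.
#' @export
track_kinematics <- function(tracks, geometry = arena_geometry(),
                             min_step = 0.1, window_frames = 5,
                             heading_from = c("auto", "orientation",
                                              "displacement"),
                             signed_turning = FALSE,
                             center_hole_mm = 0.5) {
  heading_from <- match.arg(heading_from)
  if (window_frames < 2) {
    abort_flyarena("`window_frames` must be >= 2.", "flyarena_config_error")
  }
  fps <- track_fps(tracks)
  use_orientation <- switch(heading_from,
    auto = "heading" %in% names(tracks) && any(!is.na(tracks$heading)),
    orientation = TRUE,
    displacement = FALSE)
  if (use_orientation && !"heading" %in% names(tracks)) {
    abort_flyarena("`heading_from = \"orientation\"` but tracks have no heading column.",
                   "flyarena_format_error")
  }

  out <- tracks |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      .consec = c(NA, diff(.data$frame)) == 1L,
      .dx = .data$x - dplyr::lag(.data$x),
      .dy = .data$y - dplyr::lag(.data$y),
      .step = sqrt(.data$.dx^2 + .data$.dy^2),
      speed = ifelse(.data$.consec, .data$.step * fps, NA_real_),
      heading = if (use_orientation) {
        wrap_angle(.data$heading)
      } else {
        displacement_heading(.data$.consec, .data$.step,
                             .data$.dx, .data$.dy, min_step)
      },
      dtheta = ifelse(.data$.consec,
                      wrap_angle(.data$heading - dplyr::lag(.data$heading)),
                      NA_real_),
      dtheta_abs = abs(.data$dtheta),
      dist_center = sqrt(.data$x^2 + .data$y^2),
      cos_upwind = ifelse(.data$dist_center < center_hole_mm, NA_real_,
                          cos(.data$heading - atan2(.data$y, .data$x))),
      cum_turn = roll_sum_trailing(
        if (signed_turning) .data$dtheta else .data$dtheta_abs,
        window_frames)) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::starts_with("."))
  attr(out, "fps") <- fps
  out
}

# heading from frame-to-frame displacement with a hold rule: steps smaller
# than min_step keep the previous heading; gaps reset it to NA (metrics are
# never carried across missing frames)
displacement_heading <- function(consec, step, dx, dy, min_step) {
  n <- length(step)
  defined <- !is.na(consec) & consec & step >= min_step
  h <- rep(NA_real_, n)
  h[defined] <- atan2(dy[defined], dx[defined])
  # a gap blocks carry-forward: mark it with a sentinel, fill, then clear
  gap <- is.na(consec) | !consec
  h[gap] <- Inf
  h <- locf(h)
  h[is.infinite(h)] <- NA_real_
  h
}

#' Individual kinematic primitives
#'
#' Thin wrappers around [track_kinematics()] that return a single metric
#' column; useful when only one feature is needed or for cross-checking.
#'
#' @inheritParams track_kinematics
#' @return A tibble `fly_id`, `frame`, `t`, plus the metric column.
#' @name kinematic-primitives
NULL

#' @rdname kinematic-primitives
#' @export
compute_speed <- function(tracks) {
  km <- track_kinematics(tracks, heading_from = "displacement", min_step = 0)
  km[c("fly_id", "frame", "t", "speed")]
}

#' @rdname kinematic-primitives
#' @export
compute_heading <- function(tracks, min_step = 0.1,
                            heading_from = c("auto", "orientation",
                                             "displacement")) {
  km <- track_kinematics(tracks, min_step = min_step,
                         heading_from = match.arg(heading_from))
  km[c("fly_id", "frame", "t", "heading")]
}

#' @rdname kinematic-primitives
#' @export
compute_angular_change <- function(tracks, min_step = 0.1,
                                   heading_from = c("auto", "orientation",
                                                    "displacement")) {
  km <- track_kinematics(tracks, min_step = min_step,
                         heading_from = match.arg(heading_from))
  km[c("fly_id", "frame", "t", "dtheta", "dtheta_abs")]
}

#' @rdname kinematic-primitives
#' @export
compute_cos_upwind <- function(tracks, geometry = arena_geometry(),
                               min_step = 0.1, center_hole_mm = 0.5) {
  km <- track_kinematics(tracks, geometry = geometry, min_step = min_step,
                         center_hole_mm = center_hole_mm)
  km[c("fly_id", "frame", "t", "cos_upwind")]
}

#' @rdname kinematic-primitives
#' @export
compute_distance_from_center <- function(tracks,
                                         geometry = arena_geometry()) {
  out <- tibble::as_tibble(tracks)
  out$dist_center <- sqrt(out$x^2 + out$y^2)
  out[c("fly_id", "frame", "t", "dist_center")]
}

#' @rdname kinematic-primitives
#' @param window_frames Number of inter-frame changes in the trailing sum.
#' @export
compute_cumulative_turning <- function(tracks, window_frames = 5,
                                       signed_turning = FALSE,
                                       min_step = 0.1) {
  km <- track_kinematics(tracks, min_step = min_step,
                         window_frames = window_frames,
                         signed_turning = signed_turning)
  km[c("fly_id", "frame", "t", "cum_turn")]
}
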