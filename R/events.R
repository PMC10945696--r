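#' Return-detection thresholds
#'
#' The return event is scored from the position a fly occupied at the end
#' of an LED stimulus: it must first move at least `excursion_mm` away from
#' that origin and then come back to within `return_mm` of it, both within
#' `horizon_s` after the stimulus ends.
#'
#' @param excursion_mm Minimum excursion distance (default 10 mm).
#' @param return_mm Return radius (default 3 mm).
#' @param horizon_s Time window after LED offset (default 15 s).
#' @param min_coverage Minimum fraction of the horizon a fly must be
#'   tracked for to be scored; less-covered fly-trials are excluded and
#'   counted (default 0.9).
#' @return A list of class `return_params`.
#' @export
return_params <- function(excursion_mm = 10, return_mm = 3, horizon_s = 15,
                          min_coverage = 0.9) {
  if (!(excursion_mm > return_mm && return_mm > 0)) {
    abort_flyarena("need excursion_mm > return_mm > 0.",
                   "flyarena_config_error")
  }
  if (horizon_s <= 0) {
    abort_flyarena("`horizon_s` must be positive.", "flyarena_config_error")
  }
  structure(list(excursion_mm = excursion_mm, return_mm = return_mm,
                 horizon_s = horizon_s, min_coverage = min_coverage),
            class = "return_params")
}

#' Detect a return-to-place event for one fly
#'
#' Anchors the origin `P0` at the fly's position at `t_ref` (an LED offset
#' time) and scans the following `horizon_s` seconds for an excursion of at
#' least `excursion_mm` followed, strictly later, by a return to within
#' `return_mm` of `P0`.
#'
#' @param track A single-fly `fly_tracks` tibble.
#' @param t_ref LED-offset time (seconds).
#' @param params A [return_params()] list.
#' @return A one-row tibble with logical `returned` and `excluded`
#'   (insufficient tracking coverage over the horizon; `returned` is `NA`
#'   when excluded), plus `coverage`.
#' @export
detect_return <- function(track, t_ref, params = return_params()) {
  if (length(unique(track$fly_id)) > 1L) {
    abort_flyarena("detect_return() expects a single-fly track.",
                   "flyarena_data_error")
  }
  fps <- track_fps(track)
  if (nrow(track) == 0L || t_ref < min(track$t) - 1e-9 ||
      t_ref > max(track$t) + 1 / fps) {
    abort_flyarena("`t_ref` lies outside the recording.",
                   "flyarena_argument_error")
  }
  frame_ref <- floor(t_ref * fps + 1e-9)  # frame whose interval contains t_ref
  i0 <- match(frame_ref, track$frame)
  n_expected <- round(params$horizon_s * fps)
  in_win <- track$frame > frame_ref &
    track$frame <= frame_ref + n_expected
  coverage <- sum(in_win) / n_expected
  if (is.na(i0) || coverage < params$min_coverage) {
    return(tibble::tibble(returned = NA, excluded = TRUE,
                          coverage = coverage))
  }
  p0 <- c(track$x[i0], track$y[i0])
  d <- sqrt((track$x[in_win] - p0[1])^2 + (track$y[in_win] - p0[2])^2)
  excursion_before <- dplyr::lag(cumsum(d >= params$excursion_mm) > 0,
                                 default = FALSE)
  returned <- any(d <= params$return_mm & excursion_before)
  tibble::tibble(returned = returned, excluded = FALSE, coverage = coverage)
}

#' Return probability over an activation session
#'
#' Applies [detect_return()] at every LED offset of the schedule, for every
#' fly, and pools the six trials: the return probability is the fraction of
#' non-excluded (fly, trial) pairs that returned.
#'
#' @param tracks A multi-fly `fly_tracks` tibble.
#' @param schedule An `arena_schedule` containing `led_on` epochs.
#' @param params A [return_params()] list.
#' @return A one-row tibble: `return_prob`, `n_returned`, `n_scored`,
#'   `n_excluded`, `n_trials`. All pairs excluded yields `NA` with a
#'   warning.
#' @export
return_probability <- function(tracks, schedule, params = return_params()) {
  led_on <- schedule_epochs(schedule, "led_on")
  if (nrow(led_on) == 0L) {
    abort_flyarena("schedule has no led_on epochs.", "flyarena_config_error")
  }
  fps <- track_fps(tracks)
  flies <- split(tibble::as_tibble(tracks), tracks$fly_id)
  flags <- purrr::map_dfr(flies, function(tr) {
    attr(tr, "fps") <- fps
    purrr::map_dfr(led_on$t_end, function(t_ref) {
      if (t_ref < min(tr$t) - 1e-9 || t_ref > max(tr$t) + 1 / fps) {
        return(tibble::tibble(returned = NA, excluded = TRUE, coverage = 0))
      }
      detect_return(tr, t_ref, params)
    })
  })
  scored <- flags[!flags$excluded, , drop = FALSE]
  if (nrow(scored) == 0L) {
    warning("all fly-trial pairs excluded; return probability is NA.",
            call. = FALSE)
    return(tibble::tibble(return_prob = NA_real_, n_returned = 0L,
                          n_scored = 0L, n_excluded = nrow(flags),
                          n_trials = nrow(led_on)))
  }
  tibble::tibble(
    return_prob = mean(scored$returned),
    n_returned = sum(scored$returned),
    n_scored = nrow(scored),
    n_excluded = sum(flags$excluded),
    n_trials = nrow(led_on))
}

#' Stimulus-locked ON/OFF window means
#'
#' For each LED trial, the ON window is the first `on_window_s` seconds of
#' the stimulus and the OFF window the `off_window_s` seconds immediately
#' after it ends. Walking speed, absolute angular change, and upwind
#' orientation are averaged over all flies, frames, and trials.
#'
#' @param frame_metrics Output of [track_kinematics()].
#' @param schedule An `arena_schedule` with `led_on` epochs.
#' @param on_window_s,off_window_s Window lengths in seconds (default 2).
#' @return A tidy tibble: `parameter` (`speed_ON`, `speed_OFF`,
#'   `angular_ON`, `angular_OFF`, `cos_upwind_ON`, `cos_upwind_OFF`),
#'   `value`, `n_flies`, `n_trials`.
#' @export
summarize_on_off <- function(frame_metrics, schedule,
                             on_window_s = 2, off_window_s = 2) {
  led_on <- schedule_epochs(schedule, "led_on")
  if (nrow(led_on) == 0L) {
    abort_flyarena("schedule has no led_on epochs.", "flyarena_config_error")
  }
  window_rows <- function(t0, len) {
    frame_metrics$t >= t0 & frame_metrics$t < t0 + len
  }
  on_idx <- Reduce(`|`, lapply(led_on$t_start,
                               function(t0) window_rows(t0, on_window_s)))
  off_idx <- Reduce(`|`, lapply(led_on$t_end,
                                function(t0) window_rows(t0, off_window_s)))
  pool <- function(idx, col, name) {
    vals <- frame_metrics[[col]][idx]
    if (all(is.na(vals))) {
      warning(sprintf("no data in the %s windows; value is NA.", name),
              call. = FALSE)
    }
    mean(vals, na.rm = TRUE)
  }
  metric_cols <- c(speed = "speed", angular = "dtheta_abs",
                   cos_upwind = "cos_upwind")
  tibble::tibble(
    parameter = c(paste0(names(metric_cols), "_ON"),
                  paste0(names(metric_cols), "_OFF")),
    value = unname(c(vapply(metric_cols, function(cl) pool(on_idx, cl, "ON"),
                            numeric(1)),
                     vapply(metric_cols, function(cl) pool(off_idx, cl, "OFF"),
                            numeric(1)))),
    n_flies = length(unique(frame_metrics$fly_id[on_idx | off_idx])),
    n_trials = nrow(led_on))
}

#' Change in distance from center during LED stimulation
#'
#' For each fly and LED trial, the mean distance from the arena center over
#' the chosen window minus the fly's distance from center at stimulus
#' onset; fly-trials untracked at the onset frame are excluded and counted.
#'
#' @param frame_metrics Output of [track_kinematics()] (needs
#'   `dist_center`).
#' @param schedule An `arena_schedule` with `led_on` epochs.
#' @param window `"on_full"` averages over the whole ON period (default);
#'   `"on_first2s"` over its first 2 s.
#' @param per_trial If `TRUE`, return the per-(fly, trial) deltas instead
#'   of the pooled mean.
#' @return One-row tibble `delta_dist_center`, `n_pairs`, `n_excluded`,
#'   `n_trials` (or the per-pair tibble when `per_trial = TRUE`).
#' @export
delta_distance_from_center <- function(frame_metrics, schedule,
                                       window = c("on_full", "on_first2s"),
                                       per_trial = FALSE) {
  window <- match.arg(window)
  led_on <- schedule_epochs(schedule, "led_on")
  if (nrow(led_on) == 0L) {
    abort_flyarena("schedule has no led_on epochs.", "flyarena_config_error")
  }
  fps <- attr(frame_metrics, "fps", exact = TRUE) %||%
    round(1 / stats::median(diff(sort(unique(frame_metrics$t)))))
  pairs <- purrr::map_dfr(seq_len(nrow(led_on)), function(k) {
    t_on <- led_on$t_start[k]
    t_hi <- if (window == "on_full") led_on$t_end[k] else t_on + 2
    onset_frame <- floor(t_on * fps + 1e-9)
    win <- frame_metrics[frame_metrics$t >= t_on & frame_metrics$t < t_hi, ,
                         drop = FALSE]
    onset <- frame_metrics[frame_metrics$frame == onset_frame, ,
                           drop = FALSE]
    win |>
      dplyr::group_by(.data$fly_id) |>
      dplyr::summarise(mean_dist = mean(.data$dist_center, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::full_join(
        tibble::tibble(fly_id = onset$fly_id,
                       onset_dist = onset$dist_center),
        by = "fly_id") |>
      dplyr::mutate(trial_index = led_on$trial_index[k],
                    delta = .data$mean_dist - .data$onset_dist)
  })
  if (per_trial) return(pairs)
  ok <- !is.na(pairs$delta)
  tibble::tibble(
    delta_dist_center = if (any(ok)) mean(pairs$delta[ok]) else NA_real_,
    n_pairs = sum(ok),
    n_excluded = sum(!ok),
    n_trials = nrow(led_on))
}

#' Cumulative turning during the first seconds of stimulation
#'
#' Mean of the windowed cumulative turning angle over the first
#' `window_s` seconds of every LED ON period, pooled over flies and trials.
#'
#' @inheritParams summarize_on_off
#' @param window_s Length of the post-onset window (default 2 s).
#' @return One-row tibble `parameter = "cum_turn_first2s"`, `value`,
#'   `n_flies`, `n_trials`.
#' @export
cumulative_turning_onset <- function(frame_metrics, schedule, window_s = 2) {
  led_on <- schedule_epochs(schedule, "led_on")
  if (nrow(led_on) == 0L) {
    abort_flyarena("schedule has no led_on epochs.", "flyarena_config_error")
  }
  idx <- Reduce(`|`, lapply(led_on$t_start, function(t0) {
    frame_metrics$t >= t0 & frame_metrics$t < t0 + window_s
  }))
  tibble::tibble(
    parameter = "cum_turn_first2s",
    value = mean(frame_metrics$cum_turn[idx], na.rm = TRUE),
    n_flies = length(unique(frame_metrics$fly_id[idx])),
    n_trials = nrow(led_on))
}

#' Full per-line activation summary
#'
#' Runs the whole epoch-locked battery for one genotype line's activation
#' session: ON/OFF window means, the onset cumulative-turning summary, the
#' change in distance from center, and the return probability. One row per
#' parameter — the row a line contributes to the screen matrix.
#'
#' @param tracks A `fly_tracks` tibble for one line's activation session.
#' @param schedule The `activation_v1` schedule used.
#' @param geometry An [arena_geometry()].
#' @param line_id Identifier stored in the output.
#' @param return_pars A [return_params()] list.
#' @param ... Passed to [track_kinematics()].
#' @return Tidy tibble: `line_id`, `parameter`, `value`, `n_flies`,
#'   `n_trials`.
#' @export
line_summary <- function(tracks, schedule, geometry = arena_geometry(),
                         line_id = "line", return_pars = return_params(),
                         ...) {
  km <- track_kinematics(tracks, geometry = geometry, ...)
  attr(km, "fps") <- track_fps(tracks)
  onoff <- summarize_on_off(km, schedule)
  turn <- cumulative_turning_onset(km, schedule)
  delta <- delta_distance_from_center(km, schedule)
  ret <- return_probability(tracks, schedule, return_pars)
  n_flies <- length(unique(tracks$fly_id))
  dplyr::bind_rows(
    onoff,
    turn,
    tibble::tibble(parameter = "delta_dist_center",
                   value = delta$delta_dist_center,
                   n_flies = n_flies, n_trials = delta$n_trials),
    tibble::tibble(parameter = "return_prob", value = ret$return_prob,
                   n_flies = n_flies, n_trials = ret$n_trials)) |>
    dplyr::mutate(line_id = line_id, .before = 1)
}

#' Z-score a screen matrix of line-level means
#'
#' Standardizes each parameter column across genotype lines (control line
#' included): `z = (value - mean) / sd`, with the sample (n - 1) standard
#' deviation. A parameter with zero variance, or fewer than two non-missing
#' lines, gets `NA` z-scores with a warning.
#'
#' @param line_means Tidy tibble with columns `line_id`, `parameter`,
#'   `value` — one row per line and parameter (e.g. stacked
#'   [line_summary()] outputs).
#' @return The input with a `z` column appended.
#' @export
zscore_screen <- function(line_means) {
  needed <- c("line_id", "parameter", "value")
  if (!all(needed %in% names(line_means))) {
    abort_flyarena("`line_means` needs columns line_id, parameter, value.",
                   "flyarena_format_error")
  }
  out <- line_means |>
    dplyr::group_by(.data$parameter) |>
    dplyr::mutate(
      .n_ok = sum(!is.na(.data$value)),
      .sd = stats::sd(.data$value, na.rm = TRUE),
      z = (.data$value - mean(.data$value, na.rm = TRUE)) / .data$.sd) |>
    dplyr::ungroup()
  bad <- out$.n_ok < 2L | is.na(out$.sd) | out$.sd == 0
  if (any(bad)) {
    warning(sprintf(
      "parameter(s) %s have < 2 lines or zero variance; z set to NA.",
      paste(unique(out$parameter[bad]), collapse = ", ")), call. = FALSE)
    out$z[bad] <- NA_real_
  }
  dplyr::select(out, -dplyr::starts_with("."))
}
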