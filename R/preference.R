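#' Assign each frame to an arena quadrant
#'
#' Quadrants are the four angular sectors of the arena, numbered 0..3
#' counterclockwise starting at `geometry$quadrant_phase`. Frames closer
#' than `hysteresis_mm` to a quadrant boundary (including frames near the
#' central suction hole, where every boundary meets) keep the fly's
#' previously assigned quadrant, which prevents boundary jitter from
#' flickering the assignment.
#'
#' @param tracks A `fly_tracks` tibble in arena-centered mm.
#' @param geometry An [arena_geometry()].
#' @param hysteresis_mm Distance band around the boundaries (default
#'   0.5 mm).
#' @return The tracks tibble with an integer `quadrant` column.
#' @export
assign_quadrant <- function(tracks, geometry = arena_geometry(),
                            hysteresis_mm = 0.5) {
  out <- tibble::as_tibble(tracks)
  ang <- (atan2(out$y, out$x) - geometry$quadrant_phase) %% (2 * pi)
  raw <- pmin(floor(ang / (pi / 2)), 3)
  r <- sqrt(out$x^2 + out$y^2)
  within_sector <- ang %% (pi / 2)
  boundary_dist <- r * sin(pmin(within_sector, pi / 2 - within_sector))
  ambiguous <- boundary_dist < hysteresis_mm
  assigned <- ifelse(ambiguous, NA_real_, raw)
  out$quadrant <- out |>
    dplyr::mutate(.assigned = assigned, .raw = raw) |>
    dplyr::group_by(.data$fly_id) |>
    dplyr::mutate(.q = dplyr::coalesce(locf(.data$.assigned), .data$.raw)) |>
    dplyr::pull(.data$.q) |>
    as.integer()
  attr(out, "fps") <- track_fps(tracks)
  out
}

#' Per-frame quadrant preference index
#'
#' The preference index at a frame is
#' `(flies in positively labeled quadrants - flies in the other quadrants) /
#' flies tracked that frame`, so it lies in \[-1, 1\]. Frames with no
#' tracked flies get `NA`.
#'
#' @param quadrants Output of [assign_quadrant()] (needs `frame`, `t`,
#'   `quadrant`).
#' @param labels Character vector of length 4 labeling quadrants 0..3 with
#'   exactly two labels, diagonal quadrants sharing a label (e.g.
#'   `c("paired", "unpaired", "paired", "unpaired")` or lit/unlit).
#' @param positive The label counted positively (default the label of
#'   quadrant 0).
#' @return Tibble per frame: `frame`, `t`, `n_positive`, `n_negative`,
#'   `n_total`, `pi`.
#' @export
preference_index <- function(quadrants, labels, positive = labels[1]) {
  if (length(labels) != 4L || length(unique(labels)) != 2L ||
      labels[1] != labels[3] || labels[2] != labels[4]) {
    abort_flyarena(
      "`labels` must give 4 quadrants two labels with diagonal quadrants matching.",
      "flyarena_config_error")
  }
  if (!positive %in% labels) {
    abort_flyarena("`positive` must be one of the labels.",
                   "flyarena_config_error")
  }
  ok <- !is.na(quadrants$quadrant)
  df <- quadrants[ok, , drop = FALSE]
  df$is_pos <- labels[df$quadrant + 1L] == positive
  df |>
    dplyr::group_by(.data$frame, .data$t) |>
    dplyr::summarise(n_positive = sum(.data$is_pos),
                     n_negative = sum(!.data$is_pos),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(pi = (.data$n_positive - .data$n_negative) /
                    .data$n_total) |>
    dplyr::arrange(.data$frame)
}

#' Windowed preference score of one test epoch
#'
#' Frame-wise preference index averaged over the last `window_s` seconds
#' of a chosen test epoch — the interval measure used for both the memory
#' score (last 30 s of a 60 s odor test) and the lit-quadrant preference
#' (last 5 s of a 30 s light test).
#'
#' @param tracks A `fly_tracks` tibble for the run.
#' @param schedule The run's `arena_schedule`.
#' @param geometry An [arena_geometry()].
#' @param labels Quadrant labels for this run (see [preference_index()]).
#' @param positive Label counted positively, e.g. `"paired"` or `"lit"`.
#' @param epoch_label Label of the test epochs in the schedule.
#' @param test_index Which test (by `trial_index`) to score.
#' @param window_s Length of the terminal scoring window in seconds.
#' @return Scalar: mean preference index over the window.
#' @export
test_preference <- function(tracks, schedule, geometry = arena_geometry(),
                            labels = geometry$odor_assignment,
                            positive = "paired", epoch_label = "test",
                            test_index = 2L, window_s = 30) {
  tests <- schedule_epochs(schedule, epoch_label)
  tests <- tests[tests$trial_index == test_index, , drop = FALSE]
  if (nrow(tests) != 1L) {
    abort_flyarena(sprintf("schedule has no unique %s epoch with trial_index %d.",
                           epoch_label, test_index),
                   "flyarena_config_error")
  }
  win <- list(t_start = max(tests$t_start, tests$t_end - window_s),
              t_end = tests$t_end)
  sl <- slice_epoch(tracks, win)
  q <- assign_quadrant(sl, geometry)
  pi_tc <- preference_index(q, labels, positive)
  mean(pi_tc$pi, na.rm = TRUE)
}

#' Memory score from a reciprocal pair of runs
#'
#' One biological replicate of the conditioning assay is a pair of runs
#' with the odor-reinforcement assignment swapped; the memory score is the
#' unweighted mean of the two runs' windowed preference scores, which
#' cancels any innate odor bias. With only one run the score is that run's
#' value and `single_run` is flagged.
#'
#' @param score_a,score_b Windowed preference scores of the two reciprocal
#'   runs (each from [test_preference()] with that run's own paired
#'   labels); `score_b` may be `NULL`.
#' @return One-row tibble: `score`, `n_runs`, `single_run`.
#' @export
memory_score <- function(score_a, score_b = NULL) {
  if (is.null(score_b) || is.na(score_b)) {
    return(tibble::tibble(score = score_a, n_runs = 1L, single_run = TRUE))
  }
  tibble::tibble(score = mean(c(score_a, score_b)), n_runs = 2L,
                 single_run = FALSE)
}

#' Lit-quadrant preference index
#'
#' Scores the two-test light preference protocol: in each 30 s test two
#' quadrants are lit (swapped between tests); the index is the mean
#' frame-wise preference for lit quadrants over the last `window_s`
#' seconds of each test, averaged over both tests.
#'
#' @param tracks A `fly_tracks` tibble covering both tests.
#' @param schedule A `light_preference_v1` schedule (provides the lit
#'   quadrant sets).
#' @param geometry An [arena_geometry()].
#' @param window_s Terminal scoring window per test (default 5 s).
#' @return One-row tibble: `score`, `score_test1`, `score_test2`.
#' @export
light_preference_index <- function(tracks, schedule,
                                   geometry = arena_geometry(),
                                   window_s = 5) {
  tests <- schedule_epochs(schedule, "light_quadrant_test")
  if (nrow(tests) != 2L) {
    abort_flyarena("schedule must contain exactly two light_quadrant_test epochs.",
                   "flyarena_config_error")
  }
  per_test <- vapply(seq_len(2L), function(k) {
    lit <- tests$lit_quadrants[[k]]
    labels <- ifelse(0:3 %in% lit, "lit", "unlit")
    test_preference(tracks, schedule, geometry, labels = labels,
                    positive = "lit", epoch_label = "light_quadrant_test",
                    test_index = tests$trial_index[k], window_s = window_s)
  }, numeric(1))
  tibble::tibble(score = mean(per_test), score_test1 = per_test[1],
                 score_test2 = per_test[2])
}

#' Screen lines by absolute memory score
#'
#' Flags lines whose mean memory score lies strictly outside the
#' `[-threshold, threshold]` band — the rule used to pick lines for
#' follow-up testing. The comparison is strict, so a score exactly at the
#' threshold is not flagged.
#'
#' @param scores Tibble with a `score` column (one row per line), or a
#'   numeric vector.
#' @param threshold Absolute score threshold (default 0.1).
#' @return The input tibble with a logical `flagged` column (a tibble is
#'   built around a bare numeric input).
#' @export
screening_filter <- function(scores, threshold = 0.1) {
  if (is.numeric(scores)) scores <- tibble::tibble(score = scores)
  if (!"score" %in% names(scores)) {
    abort_flyarena("`scores` needs a `score` column.",
                   "flyarena_format_error")
  }
  dplyr::mutate(scores, flagged = abs(.data$score) > threshold)
}
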