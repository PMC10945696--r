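#' Synthetic cohort configuration
#'
#' Generative parameters of a simulated arena cohort: a correlated random
#' walk per fly (persistent heading plus wrapped-normal angular noise) with
#' stimulus-coupled modulation mirroring the phenotypes the pipeline
#' measures — LED-locked speed change, extra turning at stimulus onset,
#' drift of heading toward the upwind (radially outward) direction after
#' stimulus offset, and a quadrant dwell bias implemented as a
#' crossing-probability asymmetry at quadrant boundaries.
#'
#' @param n_flies Number of flies (default 20, the standard group size).
#' @param fps Frames per second (default 30).
#' @param radius_mm Arena radius (default 50 mm; 10 cm diameter arena).
#' @param duration_s Recording length in seconds; `NULL` uses the
#'   schedule's full span.
#' @param seed Cohort seed; per-fly seeds are derived from it (see
#'   Details).
#' @param base_speed_mm_s,speed_sd_mm_s Per-frame walking speed is
#'   `max(0, Normal(base, sd))` mm/s (defaults 10 and 3).
#' @param turn_concentration Heading-persistence parameter: the
#'   wrapped-normal heading noise has variance `1 / turn_concentration`
#'   per frame (default 8, i.e. sd about 0.35 rad/frame).
#' @param led_speed_multiplier Speed multiplier while the LED is on
#'   (default 1 = no effect).
#' @param onset_turn_boost Fractional increase of heading-noise sd during
#'   the first `onset_window_s` of each LED pulse (default 0).
#' @param offset_upwind_bias Per-frame pull of heading toward the outward
#'   radial direction during `offset_window_s` after LED offset, as a
#'   fraction of the angular error corrected per frame (default 0).
#' @param quadrant_bias Probability that a step crossing out of a favored
#'   quadrant is rejected (default 0 = no bias).
#' @param bias_label Which quadrant label the bias favors (default
#'   `"paired"`).
#' @param track_dropout_rate Independent per-frame probability that a
#'   frame is lost from the track (default 0).
#' @param onset_window_s,offset_window_s Lengths of the onset/offset
#'   modulation windows (default 2 s each, matching the analysis windows).
#'
#' @details Per-fly seeds are derived from `(seed, fly index)` with a
#' multiplicative mixing chain modulo 2^31 - 1, so cohorts are exactly
#' reproducible and flies are driven by independent RNG streams.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_flies = 20, fps = 30, radius_mm = 50,
                       duration_s = NULL, seed = 1,
                       base_speed_mm_s = 10, speed_sd_mm_s = 3,
                       turn_concentration = 8,
                       led_speed_multiplier = 1, onset_turn_boost = 0,
                       offset_upwind_bias = 0, quadrant_bias = 0,
                       bias_label = "paired", track_dropout_rate = 0,
                       onset_window_s = 2, offset_window_s = 2) {
  stopifnot(n_flies >= 0, fps > 0, radius_mm > 0,
            turn_concentration > 0, led_speed_multiplier >= 0,
            onset_turn_boost >= 0, offset_upwind_bias >= 0,
            quadrant_bias >= 0, quadrant_bias < 1,
            track_dropout_rate >= 0, track_dropout_rate < 1)
  structure(
    list(n_flies = n_flies, fps = fps, radius_mm = radius_mm,
         duration_s = duration_s, seed = seed,
         base_speed_mm_s = base_speed_mm_s,
         speed_sd_mm_s = speed_sd_mm_s,
         turn_concentration = turn_concentration,
         led_speed_multiplier = led_speed_multiplier,
         onset_turn_boost = onset_turn_boost,
         offset_upwind_bias = offset_upwind_bias,
         quadrant_bias = quadrant_bias, bias_label = bias_label,
         track_dropout_rate = track_dropout_rate,
         onset_window_s = onset_window_s,
         offset_window_s = offset_window_s),
    class = "sim_config")
}

# deterministic per-fly seed: minstd multiplicative chain, exact in doubles
mix_seed <- function(seed, index) {
  m <- 2147483647
  x <- as.double(seed) %% m
  x <- (x * 48271) %% m
  x <- (x + as.double(index) * 10007 + 12345) %% m
  x <- (x * 48271) %% m
  as.integer(x)
}

# per-frame stimulus state for a schedule: is the LED on, is the frame in
# the first onset_window_s of a pulse, is it within offset_window_s after
# a pulse ends
frame_states <- function(schedule, n_frames, fps, onset_window_s,
                         offset_window_s) {
  t <- (seq_len(n_frames) - 1L) / fps
  led_on <- rep(FALSE, n_frames)
  onset <- rep(FALSE, n_frames)
  offset <- rep(FALSE, n_frames)
  eps <- schedule_epochs(schedule, "led_on")
  lit <- schedule[schedule$label == "light_quadrant_test", , drop = FALSE]
  eps <- rbind(eps[c("t_start", "t_end")], lit[c("t_start", "t_end")])
  if (nrow(eps) > 0L) {
    for (k in seq_len(nrow(eps))) {
      led_on <- led_on | (t >= eps$t_start[k] & t < eps$t_end[k])
      onset <- onset | (t >= eps$t_start[k] &
                          t < eps$t_start[k] + onset_window_s)
      offset <- offset | (t >= eps$t_end[k] &
                            t < eps$t_end[k] + offset_window_s)
    }
  }
  list(led_on = led_on, onset = onset, offset = offset)
}

#' Simulate a single fly
#'
#' One correlated random walk under a stimulus schedule; see
#' [sim_config()] for the generative model. The walk starts at a uniform
#' position within 95% of the arena radius with uniform heading, reflects
#' specularly off the wall, and stays inside the arena at all times.
#'
#' @param config A [sim_config()].
#' @param schedule An `arena_schedule` driving the stimulus modulation.
#' @param fly_seed Integer RNG seed for this fly.
#' @param fly_id Identifier stored in the output (default `"fly_1"`).
#' @return A single-fly `fly_tracks` tibble with a `heading` column;
#'   frames lost to dropout are absent (gaps, not NAs).
#' @export
simulate_fly <- function(config, schedule, fly_seed = config$seed,
                         fly_id = "fly_1") {
  fps <- config$fps
  duration <- config$duration_s %||% max(schedule$t_end)
  n_frames <- round(duration * fps)
  st <- frame_states(schedule, n_frames, fps, config$onset_window_s,
                     config$offset_window_s)
  favored <- quadrant_favored(config)
  # concentration = 1/variance of the per-frame heading noise; Inf gives a
  # noise-free (ballistic) walk
  noise_sd <- 1 / sqrt(config$turn_concentration)
  old_seed <- .Random.seed_get()
  on.exit(.Random.seed_set(old_seed), add = TRUE)
  set.seed(fly_seed)
  r0 <- config$radius_mm * 0.95 * sqrt(stats::runif(1))
  a0 <- stats::runif(1, 0, 2 * pi)
  theta0 <- stats::runif(1, -pi, pi)
  sim <- crw_simulate(
    n_frames = n_frames, dt = 1 / fps,
    x0 = r0 * cos(a0), y0 = r0 * sin(a0), theta0 = theta0,
    radius = config$radius_mm,
    base_speed = config$base_speed_mm_s, speed_sd = config$speed_sd_mm_s,
    noise_sd = noise_sd,
    led_on = st$led_on, onset_win = st$onset, offset_win = st$offset,
    speed_mult = config$led_speed_multiplier,
    onset_boost = config$onset_turn_boost,
    upwind_bias = config$offset_upwind_bias,
    q_bias = config$quadrant_bias, q_phase = 0, favored = favored)
  keep <- if (config$track_dropout_rate > 0) {
    stats::runif(n_frames) >= config$track_dropout_rate
  } else {
    rep(TRUE, n_frames)
  }
  df <- tibble::tibble(fly_id = fly_id, frame = (seq_len(n_frames) - 1L),
                       x = sim$x, y = sim$y,
                       heading = sim$theta)[keep, , drop = FALSE]
  fly_tracks(df, fps = fps)
}

quadrant_favored <- function(config) {
  assignment <- c("paired", "unpaired", "paired", "unpaired")
  assignment == config$bias_label
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(value) {
  if (!is.null(value)) {
    assign(".Random.seed", value, envir = globalenv())
  }
}

#' Simulate a cohort of flies
#'
#' Runs `n_flies` independent [simulate_fly()] walks with per-fly seeds
#' derived from the cohort seed, and binds them into one track table. The
#' generative ground truth (every imposed effect size) travels with the
#' result as the `sim_config` attribute and is written alongside fixtures
#' by [write_fixture()].
#'
#' @param config A [sim_config()].
#' @param schedule An `arena_schedule`.
#' @return A multi-fly `fly_tracks` tibble with attribute `sim_config`.
#' @examples
#' sched <- build_schedule("activation_v1")
#' cohort <- simulate_cohort(sim_config(n_flies = 2, duration_s = 30), sched)
#' @export
simulate_cohort <- function(config, schedule) {
  if (config$n_flies == 0L) {
    out <- fly_tracks(tibble::tibble(fly_id = character(), frame = integer(),
                                     x = numeric(), y = numeric(),
                                     heading = numeric()),
                      fps = config$fps)
    attr(out, "sim_config") <- config
    return(out)
  }
  flies <- purrr::map(seq_len(config$n_flies), function(i) {
    simulate_fly(config, schedule, fly_seed = mix_seed(config$seed, i),
                 fly_id = sprintf("fly_%02d", i))
  })
  out <- fly_tracks(dplyr::bind_rows(flies), fps = config$fps)
  attr(out, "sim_config") <- config
  out
}

#' Write a simulated cohort as an on-disk fixture
#'
#' Emits the three files a real experiment would provide: the tracker-style
#' track CSV, the schedule CSV, and the generative ground truth as JSON.
#' The track file is readable by [load_tracks()] with an identity
#' calibration and reproduces coordinates to well under 1e-6 mm.
#'
#' @param cohort A `fly_tracks` tibble from [simulate_cohort()].
#' @param schedule The schedule it was simulated under.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(cohort, schedule, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) {
    abort_flyarena(paste0("cannot create fixture directory: ", dir),
                   "flyarena_io_error")
  }
  paths <- c(tracks = file.path(dir, "tracks.csv"),
             schedule = file.path(dir, "schedule.csv"),
             truth = file.path(dir, "truth.json"))
  write_tracks(cohort, paths[["tracks"]])
  write_schedule(schedule, paths[["schedule"]])
  config <- attr(cohort, "sim_config", exact = TRUE)
  truth <- if (is.null(config)) list() else unclass(config)
  truth$fps <- track_fps(cohort)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
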