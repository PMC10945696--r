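test_that("return detection fires on excursion-then-return paths only", {
  fps <- 30
  n <- 16 * fps
  # out to 12 mm by t_ref+3 s, back to 1 mm by t_ref+8 s, then parked
  t <- (0:(n - 1)) / fps
  x <- approx(c(0, 3, 8, 16), c(0, 12, 1, 1), xout = t)$y
  tr <- make_track(0:(n - 1), x = x, y = rep(0, n), fps = fps)
  res <- detect_return(tr, t_ref = 0)
  expect_true(res$returned)
  expect_false(res$excluded)

  # never exceeds the 10 mm excursion threshold
  x2 <- 9 * sin(t)
  tr2 <- make_track(0:(n - 1), x = x2, y = rep(0, n), fps = fps)
  expect_false(detect_return(tr2, t_ref = 0)$returned)

  # excursion without return
  x3 <- pmin(12, 12 * t / 3)
  tr3 <- make_track(0:(n - 1), x = x3, y = rep(0, n), fps = fps)
  expect_false(detect_return(tr3, t_ref = 0)$returned)

  expect_error(detect_return(tr, t_ref = 100),
               class = "flyarena_argument_error")
})

test_that("return flags match the O(n^2) pair-scan oracle on random walks", {
  sched <- one_pulse_schedule()
  pars <- return_params()
  fps <- 30
  n_agree <- 0L
  outcomes <- logical(0)
  for (s in 1:60) {
    tr <- simulate_fly(sim_config(duration_s = 30, seed = s,
                                  base_speed_mm_s = 6), sched, fly_seed = s)
    got <- detect_return(tr, t_ref = 10, pars)
    i0 <- match(300L, tr$frame)
    win <- tr$frame > 300L & tr$frame <= 300L + pars$horizon_s * fps
    d <- sqrt((tr$x[win] - tr$x[i0])^2 + (tr$y[win] - tr$y[i0])^2)
    want <- oracle_return_scan(d, pars$excursion_mm, pars$return_mm)
    expect_identical(got$returned, want)
    outcomes <- c(outcomes, want)
  }
  # the random-walk ensemble must exercise both outcomes
  expect_true(any(outcomes) && !all(outcomes))
})

test_that("return detection is monotone in its thresholds", {
  sched <- one_pulse_schedule()
  for (s in 1:20) {
    tr <- simulate_fly(sim_config(duration_s = 30, seed = s,
                                  base_speed_mm_s = 6), sched, fly_seed = s)
    base <- detect_return(tr, 10, return_params())$returned
    harder <- list(
      return_params(excursion_mm = 14),
      return_params(return_mm = 1.5),
      return_params(horizon_s = 7))
    for (p in harder) {
      expect_true(detect_return(tr, 10, p)$returned <= base)
    }
  }
})

test_that("sparsely tracked flies are excluded from return scoring", {
  fps <- 30
  keep <- seq(1, 16 * fps, by = 2)  # 50% coverage
  t <- (keep - 1) / fps
  tr <- make_track(keep - 1L, x = 12 * sin(t), y = rep(0, length(keep)),
                   fps = fps)
  res <- detect_return(tr, t_ref = 0)
  expect_true(res$excluded)
  expect_true(is.na(res$returned))
})

test_that("return probability pools trials and ignores fly labels and order", {
  set.seed(1)
  sched <- build_schedule("activation_v1")
  cfg <- sim_config(n_flies = 6, seed = 21, base_speed_mm_s = 6)
  cohort <- simulate_cohort(cfg, sched)
  res <- return_probability(cohort, sched)
  expect_true(res$return_prob >= 0 && res$return_prob <= 1)
  expect_equal(res$n_trials, 6L)

  relabeled <- cohort
  relabeled$fly_id <- factor(relabeled$fly_id,
                             labels = sample(LETTERS[1:6]))
  relabeled <- fly_tracks(tibble::as_tibble(relabeled), fps = 30)
  expect_equal(return_probability(relabeled, sched)$return_prob,
               res$return_prob)

  shuffled_sched <- sched[sample(nrow(sched)), ]
  class(shuffled_sched) <- class(sched)
  expect_equal(return_probability(cohort, shuffled_sched)$return_prob,
               res$return_prob)
})

test_that("ON/OFF summaries recover forced values and hand-computed means", {
  sched <- one_pulse_schedule()
  fps <- 30
  n <- 14 * fps
  t <- (0:(n - 1)) / fps
  led <- t < 10
  # speed 5 mm/s during LED, 10 mm/s after; speed at frame n is the
  # displacement over (n-1, n], so the forcing keys on the arrival frame
  x <- cumsum(c(0, ifelse(led[-1], 5, 10) / fps))
  tr <- make_tracks(purrr::map_dfr(c("a", "b"), function(id) {
    tibble::tibble(fly_id = id, frame = 0:(n - 1), x = x,
                   y = ifelse(id == "a", 5, -5))
  }))
  km <- track_kinematics(tr, heading_from = "displacement")
  out <- summarize_on_off(km, sched)
  expect_equal(out$value[out$parameter == "speed_ON"], 5, tolerance = 1e-9)
  expect_equal(out$value[out$parameter == "speed_OFF"], 10,
               tolerance = 1e-9)
  expect_equal(unique(out$n_flies), 2L)

  # single fly / single trial equals a brute-force window mean
  tr1 <- simulate_fly(sim_config(duration_s = 14, seed = 2), sched,
                      fly_seed = 2)
  km1 <- track_kinematics(tr1)
  out1 <- summarize_on_off(km1, sched)
  want <- mean(km1$speed[km1$t >= 0 & km1$t < 2], na.rm = TRUE)
  expect_equal(out1$value[out1$parameter == "speed_ON"], want)
  want_off <- mean(km1$cos_upwind[km1$t >= 10 & km1$t < 12], na.rm = TRUE)
  expect_equal(out1$value[out1$parameter == "cos_upwind_OFF"], want_off)

  expect_error(summarize_on_off(km1, test_only_schedule()),
               class = "flyarena_config_error")
})

test_that("distance-from-center delta handles ramps and stationary flies", {
  sched <- one_pulse_schedule()
  fps <- 30
  n <- 12 * fps

  still <- make_track(0:(n - 1), x = rep(20, n), y = rep(0, n))
  km <- track_kinematics(still, heading_from = "displacement")
  attr(km, "fps") <- fps
  expect_equal(delta_distance_from_center(km, sched)$delta_dist_center, 0)

  # radial 10 -> 20 mm linearly over the 10 s ON period
  x <- pmin(10 + (0:(n - 1)) / fps, 20)
  ramp <- make_track(0:(n - 1), x = x, y = rep(0, n))
  km <- track_kinematics(ramp, heading_from = "displacement")
  attr(km, "fps") <- fps
  res <- delta_distance_from_center(km, sched)
  expect_equal(res$delta_dist_center, 5, tolerance = 0.02)

  # cohort result equals an explicit per-fly, per-trial loop
  sched6 <- build_schedule("activation_v1")
  cohort <- simulate_cohort(sim_config(n_flies = 4, seed = 9), sched6)
  km <- track_kinematics(cohort)
  attr(km, "fps") <- 30
  got <- delta_distance_from_center(km, sched6)
  on <- schedule_epochs(sched6, "led_on")
  deltas <- c()
  for (k in seq_len(nrow(on))) {
    for (f in unique(km$fly_id)) {
      sub <- km[km$fly_id == f, ]
      onset <- sub$dist_center[sub$frame == round(on$t_start[k] * 30)]
      w <- sub$dist_center[sub$t >= on$t_start[k] & sub$t < on$t_end[k]]
      if (length(onset) == 1L && length(w) > 0L) {
        deltas <- c(deltas, mean(w) - onset)
      }
    }
  }
  expect_equal(got$delta_dist_center, mean(deltas), tolerance = 1e-12)
  expect_equal(got$n_pairs, length(deltas))
})

test_that("z-scoring standardizes each parameter across lines", {
  df <- tibble::tibble(line_id = c("a", "b", "c"), parameter = "speed_ON",
                       value = c(1, 2, 3))
  z <- zscore_screen(df)
  expect_equal(z$z, c(-1, 0, 1))

  const <- tibble::tibble(line_id = c("a", "b"), parameter = "p",
                          value = c(2, 2))
  expect_warning(zc <- zscore_screen(const), "zero variance")
  expect_true(all(is.na(zc$z)))

  # random 20 x 9 screen: every column mean 0, sd 1; affine invariance
  set.seed(31)
  grid <- tidyr::expand_grid(line_id = sprintf("L%02d", 1:20),
                             parameter = sprintf("p%d", 1:9))
  grid$value <- rnorm(nrow(grid))
  z <- zscore_screen(grid)
  mom <- dplyr::summarise(dplyr::group_by(z, parameter),
                          m = mean(z), s = sd(z))
  expect_equal(mom$m, rep(0, 9), tolerance = 1e-12)
  expect_equal(mom$s, rep(1, 9), tolerance = 1e-12)

  affine <- dplyr::mutate(grid,
                          value = value * rep(1:9, 20) + rep(0:8, 20))
  expect_equal(zscore_screen(affine)$z, z$z, tolerance = 1e-9)
})
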