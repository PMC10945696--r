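test_that("displacement heading follows motion and holds through jitter", {
  # eastward 1 mm steps: heading 0 from frame 1 on
  tr <- make_track(0:5, x = 0:5, y = rep(0, 6))
  km <- track_kinematics(tr, heading_from = "displacement")
  expect_true(is.na(km$heading[1]))
  expect_equal(km$heading[-1], rep(0, 5))

  # northward step: heading pi/2
  tr <- make_track(0:1, x = c(0, 0), y = c(0, 1))
  km <- track_kinematics(tr, heading_from = "displacement")
  expect_equal(km$heading[2], pi / 2)

  # jitter below min_step keeps the previous heading
  tr <- make_track(0:3, x = c(0, 1, 1.01, 1.02), y = rep(0, 4))
  km <- track_kinematics(tr, heading_from = "displacement", min_step = 0.1)
  expect_equal(km$heading[2:4], rep(0, 3))
})

test_that("speed is displacement times fps, NA at gaps and first frame", {
  tr <- make_track(c(0:10, 12:14), x = c(0:10, 12:14), y = rep(0, 14))
  km <- track_kinematics(tr, heading_from = "displacement")
  expect_true(is.na(km$speed[1]))
  expect_equal(km$speed[2:11], rep(30, 10))  # 1 mm/frame at 30 fps
  expect_true(is.na(km$speed[km$frame == 12]))  # across the gap
  expect_equal(km$speed[km$frame %in% 13:14], rep(30, 2))

  still <- make_track(0:5, x = rep(1, 6), y = rep(2, 6))
  expect_equal(track_kinematics(still,
                                heading_from = "displacement")$speed[-1],
               rep(0, 5))
})

test_that("angular change wraps across the branch cut", {
  tr <- make_track(0:1, x = c(0, 0), y = c(0, 0),
                   heading = c(0.1, 2 * pi - 0.1))
  km <- track_kinematics(tr, heading_from = "orientation")
  expect_equal(km$dtheta_abs[2], 0.2, tolerance = 1e-12)

  tr <- make_track(0:1, x = c(0, 0), y = c(0, 0), heading = c(0, pi / 2))
  expect_equal(track_kinematics(tr,
                                heading_from = "orientation")$dtheta_abs[2],
               pi / 2)

  tr <- make_track(0:9, x = rep(0, 10), y = rep(0, 10),
                   heading = rep(1.3, 10))
  expect_equal(track_kinematics(tr,
                                heading_from = "orientation")$dtheta_abs[-1],
               rep(0, 9))
})

test_that("upwind cosine matches the three analytic headings at (20, 0)", {
  for (case in list(c(0, 1), c(pi / 2, 0), c(pi, -1))) {
    tr <- make_track(0:1, x = c(20, 20), y = c(0, 0),
                     heading = rep(case[1], 2))
    km <- track_kinematics(tr, heading_from = "orientation")
    expect_equal(km$cos_upwind[2], case[2], tolerance = 1e-12)
  }
  # undefined near the suction hole
  tr <- make_track(0:1, x = c(0.1, 0.1), y = c(0, 0), heading = c(0, 0))
  expect_true(all(is.na(
    track_kinematics(tr, heading_from = "orientation")$cos_upwind)))
})

test_that("cumulative turning equals the brute-force windowed sum", {
  # constant 10 deg/frame over a 5-change window -> 50 deg
  h <- cumsum(rep(10 * pi / 180, 21))
  tr <- make_track(0:20, x = rep(10, 21), y = rep(0, 21), heading = h)
  km <- track_kinematics(tr, heading_from = "orientation")
  expect_equal(km$cum_turn[7], 50 * pi / 180, tolerance = 1e-12)

  # straight walking has zero turning
  tr <- make_track(0:20, x = 0:20, y = rep(0, 21))
  km <- track_kinematics(tr, heading_from = "displacement")
  expect_equal(km$cum_turn[7:21], rep(0, 15))

  # random heading sequence vs an explicit loop over all windows
  set.seed(42)
  h <- runif(50, -pi, pi)
  tr <- make_track(0:49, x = rep(10, 50), y = rep(0, 50), heading = h)
  km <- track_kinematics(tr, heading_from = "orientation",
                         window_frames = 5)
  dth <- abs(wrap_angle(diff(h)))
  for (i in 10:50) {
    expect_equal(km$cum_turn[i], sum(dth[(i - 5):(i - 1)]),
                 tolerance = 1e-12)
  }

  # a gap poisons exactly the windows that span it
  tr <- make_track(c(0:10, 12:25), x = rep(10, 25), y = rep(0, 25),
                   heading = rep(0, 25))
  km <- track_kinematics(tr, heading_from = "orientation")
  expect_true(all(is.na(km$cum_turn[km$frame %in% 12:16])))
  expect_equal(km$cum_turn[km$frame == 17], 0)
})

test_that("distance from center is the Euclidean norm", {
  tr <- make_track(0:1, x = c(3, 0), y = c(4, 0))
  km <- track_kinematics(tr, heading_from = "displacement")
  expect_equal(km$dist_center, c(5, 0))

  set.seed(7)
  x <- runif(100, -30, 30); y <- runif(100, -30, 30)
  tr <- make_track(0:99, x = x, y = y)
  expect_equal(track_kinematics(tr,
                                heading_from = "displacement")$dist_center,
               sqrt(x^2 + y^2))
})

test_that("per-frame metrics are invariant to rotation and translation", {
  set.seed(99)
  sched <- one_pulse_schedule()
  tr <- simulate_fly(sim_config(duration_s = 20, seed = 3), sched,
                     fly_seed = 3)
  km <- track_kinematics(tr, heading_from = "displacement")

  phi <- 0.7
  rot <- tibble::tibble(
    fly_id = tr$fly_id, frame = tr$frame,
    x = cos(phi) * tr$x - sin(phi) * tr$y,
    y = sin(phi) * tr$x + cos(phi) * tr$y)
  km_rot <- track_kinematics(fly_tracks(rot), heading_from = "displacement")
  for (col in c("speed", "dtheta_abs", "cum_turn", "dist_center",
                "cos_upwind")) {
    expect_equal(km_rot[[col]], km[[col]], tolerance = 1e-9)
  }

  # translated arena: shift raw coordinates and declare the shifted center
  shift <- c(12, -8)
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(frame = tr$frame, fly_id = tr$fly_id,
                                  x = tr$x + shift[1], y = tr$y + shift[2]),
                   tmp)
  tra <- load_tracks(tmp, arena_geometry(center_x = shift[1],
                                         center_y = shift[2]))
  km_tra <- track_kinematics(tra, heading_from = "displacement")
  expect_equal(km_tra$speed, km$speed, tolerance = 1e-9)
  expect_equal(km_tra$dist_center, km$dist_center, tolerance = 1e-9)
  expect_equal(km_tra$cos_upwind, km$cos_upwind, tolerance = 1e-9)
})

test_that("metric bounds and the radial outbound benchmark hold", {
  sched <- one_pulse_schedule()
  tr <- simulate_fly(sim_config(duration_s = 30, seed = 5,
                                onset_turn_boost = 2), sched, fly_seed = 5)
  km <- track_kinematics(tr)
  expect_true(all(km$dtheta_abs <= pi + 1e-12, na.rm = TRUE))
  expect_true(all(km$cum_turn <= 5 * pi + 1e-12, na.rm = TRUE))
  expect_true(all(abs(km$cos_upwind) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(km$speed >= 0, na.rm = TRUE))

  # straight radial outbound walk: cos_upwind = +1, no turning
  tr <- make_track(0:30, x = seq(1, 31), y = rep(0, 31))
  km <- track_kinematics(tr, heading_from = "displacement")
  expect_equal(km$cos_upwind[-1], rep(1, 30), tolerance = 1e-12)
  expect_equal(km$dtheta_abs[-(1:2)], rep(0, 29))
})
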