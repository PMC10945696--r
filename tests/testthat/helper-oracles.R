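# Independent oracles, written deliberately apart from the package code:
# brute-force pair scans, loop-based rank statistics, and small fixture
# builders used across the test files.

# O(n^2) return-event oracle: scan every ordered pair (t1 < t2) of frames
# in the horizon window for excursion-then-return
oracle_return_scan <- function(d, excursion_mm, return_mm) {
  n <- length(d)
  if (n < 2) return(FALSE)
  out <- outer(d >= excursion_mm, d <= return_mm, `&`)
  any(out[upper.tri(out)])
}

# mid-ranks computed by explicit sort-and-average rather than rank()
oracle_midrank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  pos <- 1L
  while (pos <= length(x)) {
    run <- which(x[ord] == x[ord[pos]])
    run <- run[run >= pos]
    r[ord[run]] <- mean(run)
    pos <- max(run) + 1L
  }
  r
}

# loop-based Dunn many-to-one reference
oracle_dunn <- function(groups, control) {
  pooled <- unlist(groups, use.names = FALSE)
  n_tot <- length(pooled)
  r <- oracle_midrank(pooled)
  starts <- cumsum(c(1, head(lengths(groups), -1)))
  mean_ranks <- numeric(length(groups))
  for (g in seq_along(groups)) {
    idx <- seq(starts[g], length.out = lengths(groups)[g])
    mean_ranks[g] <- mean(r[idx])
  }
  names(mean_ranks) <- names(groups)
  tie_sizes <- as.numeric(table(pooled))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  s2 <- n_tot * (n_tot + 1) / 12 - tie_term / (12 * (n_tot - 1))
  ci <- match(control, names(groups))
  others <- setdiff(seq_along(groups), ci)
  z <- p <- numeric(length(others))
  for (k in seq_along(others)) {
    g <- others[k]
    se <- sqrt(s2 * (1 / lengths(groups)[g] + 1 / lengths(groups)[ci]))
    z[k] <- (mean_ranks[g] - mean_ranks[ci]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group = names(groups)[others], z = z, p = p)
}

# tracks builder: one fly on given (frame, x, y[, heading]) rows
make_track <- function(frame, x, y, heading = NULL, fly_id = "f1",
                       fps = 30) {
  df <- tibble::tibble(fly_id = fly_id, frame = frame, x = x, y = y)
  if (!is.null(heading)) df$heading <- heading
  fly_tracks(df, fps = fps)
}

# multi-fly tracks from a long data frame
make_tracks <- function(df, fps = 30) fly_tracks(df, fps = fps)

# place n flies at fixed polar positions for a run of frames
static_cohort <- function(angles_deg, r = 30, frames = 0:29, fps = 30) {
  df <- purrr::map_dfr(seq_along(angles_deg), function(i) {
    a <- angles_deg[i] * pi / 180
    tibble::tibble(fly_id = sprintf("f%02d", i), frame = frames,
                   x = r * cos(a), y = r * sin(a))
  })
  fly_tracks(df, fps = fps)
}

# a single activation-style led_on/led_off schedule with one pulse
one_pulse_schedule <- function(t_on = 0, dur = 10, off = 100) {
  sched <- tibble::tibble(
    label = c("led_on", "led_off"), channel = "led",
    t_start = c(t_on, t_on + dur), t_end = c(t_on + dur, t_on + dur + off),
    trial_index = 1L, odor = NA_character_,
    lit_quadrants = list(integer(), integer()))
  class(sched) <- c("arena_schedule", class(tibble::tibble()))
  sched
}

# schedule with a single labeled test epoch
test_only_schedule <- function(t_end = 60, label = "test") {
  sched <- tibble::tibble(
    label = label, channel = "odor", t_start = 0, t_end = t_end,
    trial_index = if (label == "test") 2L else 1L, odor = "A",
    lit_quadrants = list(integer()))
  class(sched) <- c("arena_schedule", class(tibble::tibble()))
  sched
}
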