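#' Build a labeled stimulus schedule
#'
#' Returns the full epoch list of one of the three assay protocols as a
#' tibble with columns `label`, `channel` (`"odor"` or `"led"`), `t_start`,
#' `t_end` (seconds, half-open `[t_start, t_end)`), `trial_index`, `odor`,
#' and `lit_quadrants` (list column of quadrant indices, used by the
#' lit-quadrant preference protocol). Epochs on the same channel never
#' overlap; LED pulses deliberately overlap the odor epoch they reinforce.
#'
#' Protocols:
#' \describe{
#'   \item{`conditioning_v1`}{Three training cycles and two preference
#'     tests. Each cycle pairs 60 s of odor A with 30 one-second LED pulses
#'     separated by 1 s dark, then presents 60 s of odor B unlit. A 60 s
#'     two-odor test follows cycle 1 and another follows cycle 3. In the
#'     reciprocal run the odor-pairing labels are swapped by the caller.}
#'   \item{`activation_v1`}{Six cycles of 10 s LED illumination spaced by
#'     100 s dark intervals with airflow but no odor; a trailing 100 s off
#'     epoch closes the session so post-offset metrics (2 s windows,
#'     15 s return horizon) always have room.}
#'   \item{`light_preference_v1`}{Two 30 s tests with two quadrants lit,
#'     separated by a 150 s recovery, the lit-quadrant set swapped between
#'     tests.}
#' }
#'
#' @param protocol_name One of `"conditioning_v1"`, `"activation_v1"`,
#'   `"light_preference_v1"`.
#' @param t0 Start time of the schedule in seconds (default 0).
#' @return A tibble of class `arena_schedule` with a `protocol_name`
#'   attribute.
#' @examples
#' sched <- build_schedule("activation_v1")
#' subset(sched, label == "led_on")
#' @export
build_schedule <- function(protocol_name = c("conditioning_v1",
                                             "activation_v1",
                                             "light_preference_v1"),
                           t0 = 0) {
  if (!is.character(protocol_name) ||
      !protocol_name[1] %in% c("conditioning_v1", "activation_v1",
                               "light_preference_v1")) {
    abort_flyarena(
      paste0("unknown protocol_name: ", paste(protocol_name[1], collapse = "")),
      "flyarena_config_error")
  }
  protocol_name <- protocol_name[1]
  ep <- function(label, channel, t_start, t_end, trial_index,
                 odor = NA_character_, lit_quadrants = list(integer())) {
    tibble::tibble(label = label, channel = channel, t_start = t_start,
                   t_end = t_end, trial_index = as.integer(trial_index),
                   odor = odor, lit_quadrants = lit_quadrants)
  }
  out <- switch(protocol_name,
    activation_v1 = {
      period <- 110  # 10 s on + 100 s off
      purrr::map_dfr(0:5, function(k) {
        on0 <- t0 + k * period
        dplyr::bind_rows(
          ep("led_on", "led", on0, on0 + 10, k + 1L),
          ep("led_off", "led", on0 + 10, on0 + 110, k + 1L))
      })
    },
    conditioning_v1 = {
      pulses <- function(block0, cycle) {
        purrr::map_dfr(0:29, function(j) {
          ep("led_on", "led", block0 + 2 * j, block0 + 2 * j + 1, cycle)
        })
      }
      cycle <- function(block0, k, odor_paired = "A", odor_unpaired = "B") {
        dplyr::bind_rows(
          ep("train_paired", "odor", block0, block0 + 60, k, odor_paired),
          pulses(block0, k),
          ep("train_unpaired", "odor", block0 + 60, block0 + 120, k,
             odor_unpaired))
      }
      dplyr::bind_rows(
        cycle(t0, 1L),
        ep("test", "odor", t0 + 120, t0 + 180, 1L),
        cycle(t0 + 180, 2L),
        cycle(t0 + 300, 3L),
        ep("test", "odor", t0 + 420, t0 + 480, 2L))
    },
    light_preference_v1 = {
      dplyr::bind_rows(
        ep("light_quadrant_test", "led", t0, t0 + 30, 1L,
           lit_quadrants = list(c(0L, 2L))),
        ep("recovery", "led", t0 + 30, t0 + 180, 1L),
        ep("light_quadrant_test", "led", t0 + 180, t0 + 210, 2L,
           lit_quadrants = list(c(1L, 3L))))
    })
  out <- dplyr::arrange(out, .data$t_start, .data$t_end)
  attr(out, "protocol_name") <- protocol_name
  class(out) <- c("arena_schedule", class(tibble::tibble()))
  out
}

#' Read and write schedule tables
#'
#' The on-disk form is a CSV with columns `label`, `channel`, `t_start`,
#' `t_end`, `trial_index`, `odor`, `lit_quadrants` (semicolon-separated
#' quadrant indices, empty when unused).
#'
#' @param schedule An `arena_schedule` tibble.
#' @param path CSV path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns an `arena_schedule` tibble.
#' @export
write_schedule <- function(schedule, path) {
  flat <- schedule
  flat$lit_quadrants <- vapply(schedule$lit_quadrants,
                               function(q) paste(q, collapse = ";"), "")
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           lit_quadrants = readr::col_character(),
                           odor = readr::col_character()))
  raw$lit_quadrants <- purrr::map(raw$lit_quadrants, function(s) {
    if (is.na(s) || !nzchar(s)) integer() else as.integer(strsplit(s, ";")[[1]])
  })
  raw$trial_index <- as.integer(raw$trial_index)
  out <- tibble::as_tibble(raw)
  class(out) <- c("arena_schedule", class(tibble::tibble()))
  out
}

#' Extract epochs of one label from a schedule
#' @param schedule An `arena_schedule` tibble.
#' @param label Epoch label, e.g. `"led_on"`.
#' @return The matching rows, ordered by `t_start`.
#' @export
schedule_epochs <- function(schedule, label) {
  out <- schedule[schedule$label == label, , drop = FALSE]
  dplyr::arrange(out, .data$t_start)
}
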