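#' Construct a calibrated fly track table
#'
#' A track table is a tibble with one row per (fly, frame): columns `fly_id`,
#' `frame` (non-negative integer), `t` (seconds, `frame / fps`), `x`, `y`
#' (mm, arena-centered: the arena center is the origin, x rightward,
#' y upward) and optionally `heading` (radians, counterclockwise from +x).
#' Missing frames are kept as gaps and never interpolated; downstream
#' kinematics are computed only over consecutive-frame pairs.
#'
#' @param df A data frame with columns `fly_id`, `frame`, `x`, `y` and
#'   optionally `heading`, already in arena-centered mm.
#' @param fps Frames per second of the videography (default 30).
#' @param geometry Optional [arena_geometry()]; when given, points farther
#'   than `radius * bounds_tol` from the center raise a calibration error.
#' @param bounds_tol Multiplicative tolerance on the radius bound.
#' @return A tibble of class `fly_tracks` sorted by (`fly_id`, `frame`),
#'   with an `fps` attribute.
#' @export
fly_tracks <- function(df, fps = 30, geometry = NULL, bounds_tol = 1.05) {
  required <- c("fly_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    abort_flyarena(
      paste0("track table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "flyarena_format_error")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    abort_flyarena("`fps` must be a positive scalar.", "flyarena_config_error")
  }
  out <- tibble::as_tibble(df)
  out$frame <- as.integer(out$frame)
  if (any(out$frame < 0L)) {
    abort_flyarena("`frame` must be non-negative.", "flyarena_data_error")
  }
  out <- dplyr::arrange(out, .data$fly_id, .data$frame)
  dup <- dplyr::summarise(dplyr::group_by(out, .data$fly_id),
                          dup = anyDuplicated(.data$frame) > 0L)
  if (any(dup$dup)) {
    abort_flyarena("frames must be strictly increasing within each fly.",
                   "flyarena_data_error")
  }
  out$t <- out$frame / fps
  if (!is.null(geometry)) {
    r <- sqrt(out$x^2 + out$y^2)
    if (any(r > geometry$radius * bounds_tol, na.rm = TRUE)) {
      abort_flyarena(
        sprintf("point(s) up to %.2f mm from center exceed radius %.2f mm x %.2f; check calibration.",
                max(r, na.rm = TRUE), geometry$radius, bounds_tol),
        "flyarena_calibration_error")
    }
  }
  keep <- intersect(c("fly_id", "frame", "t", "x", "y", "heading"), names(out))
  out <- out[keep]
  attr(out, "fps") <- fps
  class(out) <- c("fly_tracks", class(tibble::tibble()))
  out
}

#' Frames per second of a track table
#' @param tracks A `fly_tracks` tibble.
#' @return The `fps` attribute (scalar).
#' @export
track_fps <- function(tracks) {
  fps <- attr(tracks, "fps", exact = TRUE)
  if (is.null(fps)) {
    abort_flyarena("track table has no `fps` attribute; build it with fly_tracks() or load_tracks().",
                   "flyarena_data_error")
  }
  fps
}

#' Load tracker-output trajectories
#'
#' Reads a tracker CSV (comma-separated, header row, UTF-8) with columns
#' `frame`, `fly_id`, `x`, `y` and optionally `heading`, calibrates it to
#' arena-centered mm, and validates it against the arena geometry.
#'
#' @param path CSV file path.
#' @param geometry An [arena_geometry()] giving the center (in the file's
#'   frame), radius, and pixel calibration.
#' @param fps Frames per second (default 30).
#' @param units Either `"mm"` or `"px"`. Pixel coordinates are divided by
#'   `geometry$px_per_mm` before centering.
#' @param bounds_tol Points farther than `radius * bounds_tol` from the
#'   center after calibration raise a calibration error (default 1.05).
#' @return A `fly_tracks` tibble in arena-centered mm.
#' @export
load_tracks <- function(path, geometry, fps = 30, units = c("mm", "px"),
                        bounds_tol = 1.05) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    abort_flyarena(paste0("track file not found: ", path), "flyarena_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("frame", "fly_id", "x", "y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort_flyarena(
      paste0("track file is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "flyarena_format_error")
  }
  scale <- if (units == "px") 1 / geometry$px_per_mm else 1
  raw$x <- raw$x * scale - geometry$center_x
  raw$y <- raw$y * scale - geometry$center_y
  fly_tracks(raw, fps = fps, geometry = geometry, bounds_tol = bounds_tol)
}

#' Write a track table to CSV
#'
#' Writes arena-centered coordinates at full precision so that a
#' write/load round trip reproduces them to well under 1e-6 mm.
#'
#' @param tracks A `fly_tracks` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("frame", "fly_id", "x", "y", "heading"), names(tracks))
  readr::write_csv(tracks[cols], path, progress = FALSE)
  invisible(path)
}

#' Slice a track table to one epoch
#'
#' Keeps rows with `t` in the half-open interval `[t_start, t_end)`. Frame
#' `n` covers `[n/fps, (n+1)/fps)`, so no frame is counted in two adjacent
#' epochs. Per-fly frame numbering is preserved, so gaps remain visible to
#' downstream kinematics.
#'
#' @param tracks A `fly_tracks` tibble.
#' @param epoch A one-row data frame (e.g. one row of a schedule) or a list
#'   with `t_start` and `t_end` in seconds.
#' @return A `fly_tracks` tibble restricted to the epoch. An empty result,
#'   or an epoch extending past the recording, produces a warning.
#' @export
slice_epoch <- function(tracks, epoch) {
  t_start <- epoch$t_start
  t_end <- epoch$t_end
  if (length(t_start) != 1L || length(t_end) != 1L || t_end < t_start) {
    abort_flyarena("epoch must have scalar t_start <= t_end.",
                   "flyarena_config_error")
  }
  fps <- track_fps(tracks)
  last_covered <- if (nrow(tracks) > 0L) max(tracks$t) + 1 / fps else 0
  if (nrow(tracks) > 0L && t_end > last_covered + 1e-9) {
    warning(sprintf("epoch [%g, %g) extends past the recording (ends %.3f s); slice truncated.",
                    t_start, t_end, last_covered), call. = FALSE)
  }
  out <- tracks[tracks$t >= t_start & tracks$t < t_end, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning(sprintf("epoch [%g, %g) contains no tracked frames.",
                    t_start, t_end), call. = FALSE)
  }
  attr(out, "fps") <- fps
  class(out) <- c("fly_tracks", class(tibble::tibble()))
  out
}
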