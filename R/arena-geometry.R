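#' Arena geometry and calibration
#'
#' Describes the circular four-quadrant arena: its center and radius in mm,
#' the pixel-to-mm calibration of the tracker, the angular phase of the first
#' quadrant boundary, and the two-and-two assignment of odor (or light)
#' labels to quadrants. Air is drawn out through a hole at the center, so the
#' upwind direction at any point is radially outward.
#'
#' Quadrant `k` (k = 0..3) is the angular sector
#' `[quadrant_phase + k * pi/2, quadrant_phase + (k + 1) * pi/2)` measured
#' counterclockwise from +x about the center. Diagonally opposite quadrants
#' carry the same label, matching the arena's paired odor delivery.
#'
#' @param center_x,center_y Arena center, mm (in the raw coordinate frame of
#'   the tracker output, before centering).
#' @param radius Arena radius in mm. The standard arena is 10 cm diameter,
#'   so `radius = 50`.
#' @param px_per_mm Pixels per mm of the video calibration; used when tracks
#'   are loaded in pixel units.
#' @param quadrant_phase Angle (radians, counterclockwise from +x) of the
#'   first quadrant boundary. The assay does not fix this relative to the
#'   odor inlets, so it is a calibration parameter.
#' @param odor_assignment Character vector of length 4 giving the label of
#'   quadrants 0..3. Must use exactly two labels with diagonal quadrants
#'   (0 and 2, 1 and 3) sharing a label, e.g.
#'   `c("paired", "unpaired", "paired", "unpaired")`.
#' @return An object of class `arena_geometry`.
#' @examples
#' geom <- arena_geometry()
#' geom$radius
#' @export
arena_geometry <- function(center_x = 0, center_y = 0, radius = 50,
                           px_per_mm = 1, quadrant_phase = 0,
                           odor_assignment = c("paired", "unpaired",
                                               "paired", "unpaired")) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort_flyarena("`radius` must be a positive scalar (mm).",
                   "flyarena_config_error")
  }
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || px_per_mm <= 0) {
    abort_flyarena("`px_per_mm` must be a positive scalar.",
                   "flyarena_config_error")
  }
  if (length(odor_assignment) != 4L ||
      length(unique(odor_assignment)) != 2L ||
      odor_assignment[1] != odor_assignment[3] ||
      odor_assignment[2] != odor_assignment[4]) {
    abort_flyarena(
      "`odor_assignment` must label 4 quadrants with two labels, diagonal quadrants sharing a label.",
      "flyarena_config_error")
  }
  structure(
    list(center_x = center_x, center_y = center_y, radius = radius,
         px_per_mm = px_per_mm, quadrant_phase = quadrant_phase,
         odor_assignment = odor_assignment),
    class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("<arena_geometry>\n")
  cat(sprintf("  center: (%.2f, %.2f) mm, radius: %.1f mm\n",
              x$center_x, x$center_y, x$radius))
  cat(sprintf("  px_per_mm: %.3f, quadrant_phase: %.3f rad\n",
              x$px_per_mm, x$quadrant_phase))
  cat("  quadrants 0..3:", paste(x$odor_assignment, collapse = ", "), "\n")
  invisible(x)
}

#' Read and write arena geometry configuration
#'
#' Plain-text key-value configuration (one `key: value` per line; units are
#' mm for lengths, radians for angles). `odor_assignment` is a comma-separated
#' list of four quadrant labels.
#'
#' @param path File path.
#' @param geometry An `arena_geometry` object (for writing).
#' @return `read_geometry()` returns an `arena_geometry`;
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) {
    abort_flyarena(paste0("geometry file not found: ", path),
                   "flyarena_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  get_num <- function(key, default) {
    if (key %in% keys) as.numeric(vals[match(key, keys)]) else default
  }
  assign <- if ("odor_assignment" %in% keys) {
    trimws(strsplit(vals[match("odor_assignment", keys)], ",")[[1]])
  } else {
    c("paired", "unpaired", "paired", "unpaired")
  }
  arena_geometry(
    center_x = get_num("center_x", 0),
    center_y = get_num("center_y", 0),
    radius = get_num("radius", 50),
    px_per_mm = get_num("px_per_mm", 1),
    quadrant_phase = get_num("quadrant_phase", 0),
    odor_assignment = assign)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "arena_geometry"))
  writeLines(c(
    sprintf("center_x: %.9g", geometry$center_x),
    sprintf("center_y: %.9g", geometry$center_y),
    sprintf("radius: %.9g", geometry$radius),
    sprintf("px_per_mm: %.9g", geometry$px_per_mm),
    sprintf("quadrant_phase: %.9g", geometry$quadrant_phase),
    paste0("odor_assignment: ",
           paste(geometry$odor_assignment, collapse = ","))), path)
  invisible(path)
}
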