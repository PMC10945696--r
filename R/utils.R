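#' Wrap an angle into (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped to the principal branch.
#' @examples
#' wrap_angle(2 * pi - 0.1) # -0.1
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps the branch point to -pi; the convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

# last-observation-carried-forward; leading NAs stay NA
locf <- function(x) {
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  x[replace(idx, idx == 0L, NA_integer_)]
}

# trailing rolling sum over exactly `k` values; NA wherever the window
# contains an NA or extends past the start
roll_sum_trailing <- function(x, k) {
  if (length(x) < k) return(rep(NA_real_, length(x)))
  as.numeric(stats::filter(x, rep(1, k), sides = 1))
}

abort_flyarena <- function(message, class) {
  rlang::abort(message, class = c(class, "flyarena_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
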