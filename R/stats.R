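#' Kruskal-Wallis rank test with tie correction
#'
#' Rank-based k-sample test on pooled mid-ranks. The statistic is
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \frac{N+1}{2})^2}
#'            {1 - \sum (t^3 - t) / (N^3 - N)}}
#' where the sum in the denominator runs over groups of tied values, and
#' the p-value is from the chi-square distribution with k - 1 degrees of
#' freedom. When every pooled value is identical the tie correction is
#' degenerate and the test returns `H = 0`, `p = 1`.
#'
#' @param data A data frame (then give `value` and `group` columns), or a
#'   list of numeric vectors, one per group.
#' @param value,group Column names (tidy-eval) when `data` is a data
#'   frame.
#' @return An object of class `kw_test` with elements `statistic` (H),
#'   `df`, `p.value`, `n`, `k`; see [tidy.kw_test()] / [glance.kw_test()].
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskal_wallis <- function(data, value = NULL, group = NULL) {
  groups <- as_group_list(data, {{ value }}, {{ group }})
  if (length(groups) < 2L) {
    abort_flyarena("need at least 2 groups.", "flyarena_argument_error")
  }
  if (any(lengths(groups) < 1L)) {
    abort_flyarena("every group needs at least one observation.",
                   "flyarena_argument_error")
  }
  pooled <- unlist(groups, use.names = FALSE)
  n_tot <- length(pooled)
  if (n_tot < 3L) {
    abort_flyarena("need at least 3 observations in total.",
                   "flyarena_argument_error")
  }
  k <- length(groups)
  r <- rank(pooled)  # mid-ranks for ties
  idx <- rep(seq_along(groups), lengths(groups))
  mean_ranks <- tapply(r, idx, mean)
  n_i <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  correction <- 1 - tie_term / (n_tot^3 - n_tot)
  if (correction <= 0) {  # all values identical
    h <- 0
  } else {
    h <- (12 / (n_tot * (n_tot + 1)) *
            sum(n_i * (mean_ranks - (n_tot + 1) / 2)^2)) / correction
  }
  structure(
    list(statistic = h, df = k - 1L,
         p.value = stats::pchisq(h, k - 1L, lower.tail = FALSE),
         n = n_i, k = k, mean_ranks = as.numeric(mean_ranks),
         method = "Kruskal-Wallis rank test (tie-corrected)"),
    class = "kw_test")
}

#' Dunn's many-to-one post test against a control group
#'
#' Rank-based multiple comparisons of every group against a designated
#' control, on the mid-ranks of the full pooled sample (not pairwise
#' re-ranking). For group i versus control c,
#' \deqn{z_i = \frac{\bar R_i - \bar R_c}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12 (N-1)}\right)
#'          \left(\frac{1}{n_i} + \frac{1}{n_c}\right)}}}
#' with a two-sided normal p-value. Bonferroni adjustment multiplies each
#' p by the number of control comparisons, capped at 1; both adjusted and
#' unadjusted p-values are always reported.
#'
#' @inheritParams kruskal_wallis
#' @param control Name (or list index) of the control group.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return An object of class `dunn_test`; [tidy.dunn_test()] gives one
#'   row per non-control group with `z`, `p.value`, `p.adjusted`,
#'   `stars`.
#' @examples
#' dunn_vs_control(list(control = c(1, 2, 3), test = c(4, 5, 6)),
#'                 control = "control")
#' @export
dunn_vs_control <- function(data, value = NULL, group = NULL, control,
                            adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- as_group_list(data, {{ value }}, {{ group }})
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning(sprintf("dropping empty group(s): %s",
                    paste(names(groups)[empty], collapse = ", ")),
            call. = FALSE)
    groups <- groups[!empty]
  }
  nm <- names(groups) %||% as.character(seq_along(groups))
  control_name <- if (is.numeric(control)) nm[control] else as.character(control)
  if (!control_name %in% nm) {
    abort_flyarena(sprintf("control group '%s' not found.", control_name),
                   "flyarena_argument_error")
  }
  if (length(groups[[control_name]]) == 0L) {
    abort_flyarena("control group is empty.", "flyarena_argument_error")
  }
  pooled <- unlist(groups, use.names = FALSE)
  n_tot <- length(pooled)
  r <- rank(pooled)
  idx <- rep(nm, lengths(groups))
  mean_ranks <- tapply(r, idx, mean)[nm]
  n_i <- stats::setNames(lengths(groups), nm)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n_tot * (n_tot + 1) / 12 - tie_term / (12 * (n_tot - 1))
  others <- setdiff(nm, control_name)
  m <- length(others)
  comp <- purrr::map_dfr(others, function(g) {
    se <- sqrt(sigma2 * (1 / n_i[[g]] + 1 / n_i[[control_name]]))
    z <- if (se > 0) {
      (mean_ranks[[g]] - mean_ranks[[control_name]]) / se
    } else {
      0
    }
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group = g, n = n_i[[g]], mean_rank = mean_ranks[[g]],
                   z = z, p.value = p,
                   p.adjusted = if (adjust == "bonferroni") {
                     min(1, p * m)
                   } else {
                     p
                   })
  })
  comp$stars <- p_stars(comp$p.adjusted)
  structure(
    list(comparisons = comp, control = control_name,
         n_control = n_i[[control_name]],
         mean_rank_control = mean_ranks[[control_name]],
         adjust = adjust, n_comparisons = m,
         method = "Dunn's many-to-one test (tie-corrected)"),
    class = "dunn_test")
}

# normalize data-frame or list input to a named list of numeric vectors
as_group_list <- function(data, value, group) {
  if (is.data.frame(data)) {
    value <- rlang::enquo(value)
    group <- rlang::enquo(group)
    if (rlang::quo_is_null(value) || rlang::quo_is_null(group)) {
      abort_flyarena("with a data frame, give `value` and `group` columns.",
                     "flyarena_argument_error")
    }
    v <- rlang::eval_tidy(value, data)
    g <- rlang::eval_tidy(group, data)
    split(as.numeric(v), factor(g, levels = unique(g)))
  } else if (is.list(data)) {
    out <- lapply(data, as.numeric)
    if (is.null(names(out))) names(out) <- as.character(seq_along(out))
    out
  } else {
    abort_flyarena("`data` must be a data frame or a list of numeric vectors.",
                   "flyarena_argument_error")
  }
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("H = %.4f, df = %d, p = %.4g (k = %d groups, N = %d)\n",
              x$statistic, x$df, x$p.value, x$k, sum(x$n)))
  invisible(x)
}

#' @export
print.dunn_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("control: %s (n = %d), %d comparisons, %s adjustment\n",
              x$control, x$n_control, x$n_comparisons, x$adjust))
  print(x$comparisons)
  invisible(x)
}

#' Tidy methods for the rank tests
#'
#' `tidy()` returns the per-comparison (Dunn) or one-row (Kruskal-Wallis)
#' results as a tibble; `glance()` returns a one-row model summary.
#'
#' @param x A `kw_test` or `dunn_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.kw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 method = x$method)
}

#' @rdname tidy.kw_test
#' @export
glance.kw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n.groups = x$k, n.total = sum(x$n))
}

#' @rdname tidy.kw_test
#' @export
tidy.dunn_test <- function(x, ...) {
  x$comparisons
}

#' @rdname tidy.kw_test
#' @export
glance.dunn_test <- function(x, ...) {
  tibble::tibble(control = x$control, n.control = x$n_control,
                 n.comparisons = x$n_comparisons, adjust = x$adjust)
}

#' @export
generics::tidy

#' @export
generics::glance
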