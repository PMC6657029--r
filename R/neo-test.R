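# Light container for a statistical contrast: statistic, raw and (optionally
# BH-adjusted) p-value, sample sizes. tidy()/glance() return one-row tibbles
# so families of contrasts bind into tables.

new_neo_test <- function(contrast, test, statistic, p_value, n1, n2,
                         degenerate = FALSE, adjusted_p = NA_real_) {
  structure(
    list(contrast = contrast, test = test, statistic = statistic,
         raw_p = p_value, adjusted_p = adjusted_p, n1 = n1, n2 = n2,
         degenerate = degenerate),
    class = "neo_test"
  )
}

#' @export
print.neo_test <- function(x, ...) {
  cat(sprintf("<neo_test> %s (%s)\n", x$contrast, x$test))
  cat(sprintf("  statistic = %s, p = %.4g%s, n = %d/%d%s\n",
              format(x$statistic), x$raw_p,
              if (!is.na(x$adjusted_p)) sprintf(" (BH %.4g)", x$adjusted_p)
              else "",
              x$n1, x$n2,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Tidy a statistical contrast
#'
#' One row per contrast with the statistic, raw and BH-adjusted p-values and
#' group sizes; `glance()` is an alias with the same shape.
#'
#' @param x A `"neo_test"` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.neo_test <- function(x, ...) {
  tibble(contrast = x$contrast, test = x$test, statistic = x$statistic,
         raw_p = x$raw_p, adjusted_p = x$adjusted_p,
         n1 = x$n1, n2 = x$n2, degenerate = x$degenerate)
}

#' @rdname tidy.neo_test
#' @export
glance.neo_test <- function(x, ...) tidy.neo_test(x, ...)

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
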