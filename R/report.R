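#' Percent of control
#'
#' Expresses a measured value as a percentage of its control (untreated
#' sample, or wild type), the reporting convention for treatment-response
#' figures: `100 * value / control`. Scale-invariant: multiplying both
#' arguments by the same positive factor changes nothing.
#'
#' @param value Nonnegative measured value(s).
#' @param control Positive control value(s).
#' @return Percentage(s).
#' @examples
#' percent_of_control(0.25, 1)  # 25
#' @export
percent_of_control <- function(value, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop("control must be finite and > 0")
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("value must be finite and >= 0")
  }
  100 * value / control
}

#' Two-sample Student t comparison
#'
#' Equal-variance (pooled) two-sample Student t test between two groups of
#' measurements, two-sided, with significance recorded against `alpha`.
#' The equal-variance form is the default; set `welch = TRUE` for the
#' unequal-variance alternative.
#'
#' @param group_a,group_b Numeric vectors; `length(group_a) >= 2`,
#'   `length(group_b) >= 1`, total `>= 3`, pooled variance `> 0`.
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch correction instead of pooled variance.
#' @return An object of class `group_comparison` with `mean_a`, `mean_b`,
#'   `t`, `df`, `p`, `n_a`, `n_b`, `alpha`, `significant`.
#' @examples
#' student_t(c(1, 2, 3), c(3, 4, 5))  # t = -2.449, df = 4
#' @export
student_t <- function(group_a, group_b, alpha = 0.05, welch = FALSE) {
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2L || n_b < 1L || n_a + n_b < 3L) {
    stop("need n_a >= 2, n_b >= 1 and n_a + n_b >= 3")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  tt <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = !welch),
    error = function(e) {
      stop("degenerate data for the t test: ", conditionMessage(e))
    })
  structure(
    list(mean_a = mean(group_a), mean_b = mean(group_b),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, n_a = n_a, n_b = n_b, alpha = alpha,
         significant = tt$p.value <= alpha,
         welch = welch),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s two-sample t: t = %.4g, df = %.4g, p = %.3g %s\n",
              if (x$welch) "Welch" else "Student", x$t, x$df, x$p,
              if (x$significant) paste0("(significant at alpha = ", x$alpha, ")")
              else paste0("(not significant at alpha = ", x$alpha, ")")))
  cat(sprintf("  group means: %.4g (n = %d) vs %.4g (n = %d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}
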