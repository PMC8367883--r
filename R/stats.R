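# Condition comparisons. Replicate counts in this assay are small (n = 3) and
# group spreads visibly unequal, so the unequal-variance (Welch) two-sample
# t-test is used throughout, computed from summary statistics so published
# mean +/- sd tables can be compared directly.

#' Significance stars for a p-value
#'
#' Exact step function at the conventional cutoffs: `***` for P <= 0.001,
#' `**` for P <= 0.01, `*` for P <= 0.05, empty otherwise.
#'
#' @param p A p-value.
#' @return One of `""`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
}

#' Welch two-sample t-test from summary statistics
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom, computed from group means, standard deviations and sizes.
#' Equivalent to `t.test(x, y)` on the raw data when the summaries are the
#' sample mean and sd of that data.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (sd with the n-1
#'   denominator; n1 >= 2).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A `dida_comparison`: `t_statistic`, `degrees_freedom` (fractional),
#'   `p_value`, `significance_stars`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (!is_count(n1) || !is_count(n2) || n1 < 2 || n2 < 2)
    stop_input("both groups need n >= 2 replicates")
  if (sd1 < 0 || sd2 < 0) stop_input("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(structure(list(t_statistic = 0,
                            degrees_freedom = n1 + n2 - 2,
                            p_value = 1,
                            significance_stars = ""),
                       class = "dida_comparison"))
    }
    stop_input("degenerate variance: both sds are 0 with unequal means")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t_statistic = t_stat,
                 degrees_freedom = df,
                 p_value = p,
                 significance_stars = significance_stars(p)),
            class = "dida_comparison")
}

#' @export
print.dida_comparison <- function(x, ...) {
  cat(sprintf("<dida_comparison> t = %.4f, df = %.3f, p = %.4g %s\n",
              x$t_statistic, x$degrees_freedom, x$p_value,
              x$significance_stars))
  invisible(x)
}
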