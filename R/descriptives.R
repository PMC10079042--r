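# Epoch-wise descriptive comparisons: Welch t or rank-sum for continuous
# variables, Pearson chi-squared (no continuity correction) for proportions.

comparison_row <- function(variable, summary_before, summary_after,
                           test_name, statistic, p_value) {
  data.frame(variable = variable, summary_before = summary_before,
             summary_after = summary_after, test_name = test_name,
             statistic = statistic, p_value = p_value,
             stringsAsFactors = FALSE)
}

.fmt_mean_sd <- function(x) sprintf("%.1f ± %.2f", mean(x), stats::sd(x))
.fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.1f (%.1f–%.1f)", q[2], q[1], q[3])
}

#' Compare a continuous variable between epochs
#'
#' Welch's two-sample t test (summarised as mean +/- sd) or the two-sample
#' Wilcoxon rank-sum test (summarised as median (IQR)). The rank-sum test
#' is the independent-groups analogue used for skewed variables; there is
#' no pairing between epochs.
#'
#' @param x,y Numeric samples for the before and after epochs.
#' @param method `"welch_t"` or `"wilcoxon_rank_sum"`.
#' @param variable Label for the output row.
#' @return A one-row data frame (variable, per-epoch summary, test name,
#'   statistic, two-sided p-value).
#' @export
compare_continuous <- function(x, y, method = c("welch_t", "wilcoxon_rank_sum"),
                               variable = "") {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (method == "welch_t") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      message("both samples constant and equal; p = 1 by convention")
      return(comparison_row(variable, .fmt_mean_sd(x), .fmt_mean_sd(y),
                            "welch_t", 0, 1))
    }
    ht <- stats::t.test(x, y)
    comparison_row(variable, .fmt_mean_sd(x), .fmt_mean_sd(y), "welch_t",
                   unname(ht$statistic), ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    comparison_row(variable, .fmt_median_iqr(x), .fmt_median_iqr(y),
                   "wilcoxon_rank_sum", unname(ht$statistic), ht$p.value)
  }
}

#' Compare two proportions between epochs
#'
#' Pearson chi-squared test on the 2x2 table, without Yates continuity
#' correction.
#'
#' @param a,n1 Events and total in the before epoch.
#' @param c,n2 Events and total in the after epoch.
#' @param variable Label for the output row.
#' @return A one-row data frame as in [compare_continuous()].
#' @export
compare_proportions <- function(a, n1, c, n2, variable = "") {
  stopifnot(a >= 0, c >= 0, a <= n1, c <= n2)
  tab <- matrix(c(a, n1 - a, c, n2 - c), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: a margin is zero, p-value undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  comparison_row(variable,
                 sprintf("%d (%.1f%%)", a, 100 * a / n1),
                 sprintf("%d (%.1f%%)", c, 100 * c / n2),
                 "chi_squared", unname(ht$statistic), ht$p.value)
}

#' Descriptive epoch comparison table
#'
#' Builds baseline-characteristics rows comparing the two epochs:
#' maternal age and BMI (Welch t), parity and breech rate (chi-squared).
#'
#' @param records Cohort data frame (post-exclusion).
#' @param epoch An [epoch_spec()].
#' @return Data frame of comparison rows.
#' @export
describe_epochs <- function(records, epoch) {
  ep <- assign_epoch(records, epoch)
  b <- records[ep == levels(ep)[1], , drop = FALSE]
  a <- records[ep == levels(ep)[2], , drop = FALSE]
  if (!nrow(b) || !nrow(a)) stop("both epochs must contain records")
  prop_row <- function(var, flag_b, flag_a) {
    compare_proportions(sum(flag_b, na.rm = TRUE), sum(!is.na(flag_b)),
                        sum(flag_a, na.rm = TRUE), sum(!is.na(flag_a)),
                        variable = var)
  }
  rbind(
    compare_continuous(b$maternal_age_years, a$maternal_age_years,
                       "welch_t", "maternal_age_years"),
    compare_continuous(b$bmi, a$bmi, "welch_t", "bmi"),
    prop_row("parous", b$parous, a$parous),
    prop_row("breech_presentation",
             b$presentation_at_birth == "breech",
             a$presentation_at_birth == "breech")
  )
}
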