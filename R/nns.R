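#' Number needed to scan
#'
#' Reciprocal of the absolute risk difference between epochs: the number
#' of women who would need to be scanned under the new policy to prevent
#' one event (here, one undiagnosed breech presentation). The point
#' estimate is `ceiling(1 / RD)`. The confidence interval inverts the Wald
#' interval for the risk difference, `RD +/- 1.959964 * SE` with
#' `SE = sqrt(p1 (1 - p1) / n1 + p2 (1 - p2) / n2)`, and rounds the
#' endpoints outward (lower floor, upper ceiling); nearest-integer
#' rounding of the same inverted bounds differs by at most one.
#'
#' @param summary A [cohort_summary()] with before risk above after risk
#'   (computed from current population numbers only, with no external
#'   information).
#' @return List with `nns` (integer), `ci` (integer pair; upper is `Inf`
#'   when the risk-difference interval crosses zero), `rd` and `rd_ci`.
#' @export
number_needed_to_scan <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  p1 <- summary$events[1] / summary$totals[1]
  p2 <- summary$events[2] / summary$totals[2]
  rd <- p1 - p2
  if (rd <= 0) stop("no reduction; NNS undefined (risk difference <= 0)")
  se <- sqrt(p1 * (1 - p1) / summary$totals[1] + p2 * (1 - p2) / summary$totals[2])
  rd_ci <- c(rd - .z975 * se, rd + .z975 * se)
  upper <- if (rd_ci[1] <= 0) Inf else ceiling(1 / rd_ci[1])
  list(nns = as.integer(ceiling(1 / rd)),
       ci = c(lower = floor(1 / rd_ci[2]), upper = upper),
       rd = rd, rd_ci = rd_ci)
}
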