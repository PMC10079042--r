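# Interrupted time-series analysis of monthly undiagnosed-breech counts
# across the policy change: a secular spline trend plus an epoch indicator
# whose contribution is tested with an ANCOVA-style F test.

#' Aggregate term breech records into a monthly series
#'
#' Bins records by calendar month from the first to the last observed
#' month with no silent gaps (months without births appear as explicit
#' zero-exposure bins). `counts` is the number of undiagnosed breech
#' presentations per month, `exposure` the number of records per month.
#' A month belongs to the "after" epoch when its first day is on or after
#' the epoch cut date; partial first/last months keep their true
#' exposures.
#'
#' @param records Cohort data frame filtered to term breech births.
#' @param epoch An [epoch_spec()].
#' @return Object of class `monthly_series`: a data frame with
#'   `month_index`, `month` (Date, first day), `counts`, `exposure`,
#'   `after`.
#' @export
aggregate_monthly <- function(records, epoch) {
  if (!nrow(records)) stop("no records to aggregate")
  stopifnot(inherits(epoch, "epoch_spec"))
  month0 <- function(d) as.Date(format(d, "%Y-%m-01"))
  m <- month0(records$birth_date)
  months <- seq(min(m), max(m), by = "month")
  undiag <- classify_undiagnosed_breech(records)
  counts <- vapply(months, function(mm) sum(undiag[m == mm]), 0L)
  exposure <- vapply(months, function(mm) sum(m == mm), 0L)
  out <- data.frame(month_index = seq_along(months), month = months,
                    counts = as.integer(counts),
                    exposure = as.integer(exposure),
                    after = months >= epoch$cut_date)
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' Build a monthly series from vectors
#'
#' For simulation studies and tests: wraps pre-computed monthly counts and
#' exposures as a `monthly_series`.
#'
#' @param counts Non-negative integer event counts per month.
#' @param exposure Births per month (`counts <= exposure`).
#' @param after Logical epoch indicator per month.
#' @return A `monthly_series`.
#' @export
monthly_series <- function(counts, exposure, after) {
  stopifnot(length(counts) == length(exposure),
            length(counts) == length(after))
  if (any(counts < 0) || any(counts > exposure)) {
    stop("need 0 <= counts <= exposure")
  }
  out <- data.frame(month_index = seq_along(counts),
                    month = as.Date(NA),
                    counts = as.integer(counts),
                    exposure = as.integer(exposure),
                    after = as.logical(after))
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' Interrupted time-series fit
#'
#' Least-squares regression of monthly counts on a natural cubic spline in
#' time plus an epoch indicator; the epoch (level-shift) effect is tested
#' by an F test comparing the models with and without the indicator,
#' holding the secular trend. A Poisson alternative with a log-exposure
#' offset replaces the F test with a likelihood-ratio test.
#'
#' @param series A `monthly_series`.
#' @param spline_df Degrees of freedom of the natural spline trend.
#' @param family `"gaussian"` (default) or `"poisson"`.
#' @return Object of class `its_result`: `fitted_trend` (fitted values per
#'   month), `epoch_effect` (coefficient on the indicator),
#'   `f_statistic`, `p_value`, `spline_df`, `family`, `model`.
#' @export
fit_its <- function(series, spline_df = 4, family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  stopifnot(inherits(series, "monthly_series"), spline_df >= 1)
  t <- series$month_index; y <- series$counts; after <- series$after

  one_epoch <- length(unique(after)) == 1L
  if (!one_epoch && (sum(after) < 2 || sum(!after) < 2)) {
    stop("need at least 2 months in each epoch")
  }

  basis <- splines::ns(t, df = spline_df)
  if (one_epoch) {
    # indicator constant: model reduces to the trend alone, no epoch effect
    m0 <- stats::lm(y ~ basis)
    return(structure(list(fitted_trend = unname(stats::fitted(m0)),
                          epoch_effect = 0, f_statistic = 0, p_value = 1,
                          spline_df = spline_df, family = family, model = m0),
                     class = "its_result"))
  }

  if (family == "gaussian") {
    m1 <- stats::lm(y ~ basis + after)
    if (anyNA(stats::coef(m1))) {
      stop("collinear design: the epoch indicator is confounded with the ",
           "spline basis; refit with fewer spline df")
    }
    m0 <- stats::lm(y ~ basis)
    an <- stats::anova(m0, m1)
    stat <- an$F[2]; pval <- an$`Pr(>F)`[2]
  } else {
    off <- log(series$exposure)
    m1 <- stats::glm(y ~ basis + after + offset(off), family = stats::poisson())
    if (anyNA(stats::coef(m1))) {
      stop("collinear design: the epoch indicator is confounded with the ",
           "spline basis; refit with fewer spline df")
    }
    m0 <- stats::glm(y ~ basis + offset(off), family = stats::poisson())
    an <- stats::anova(m0, m1, test = "LRT")
    stat <- an$Deviance[2]; pval <- an$`Pr(>Chi)`[2]
  }
  structure(list(fitted_trend = unname(stats::fitted(m1)),
                 epoch_effect = unname(stats::coef(m1)[["afterTRUE"]]),
                 f_statistic = unname(stat), p_value = unname(pval),
                 spline_df = spline_df, family = family, model = m1),
            class = "its_result")
}

#' @export
print.its_result <- function(x, ...) {
  cat(sprintf("ITS (%s, spline df = %d): epoch effect %.3f, %s = %.2f, p = %.4g\n",
              x$family, x$spline_df, x$epoch_effect,
              if (x$family == "gaussian") "F" else "LR", x$f_statistic,
              x$p_value))
  invisible(x)
}
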