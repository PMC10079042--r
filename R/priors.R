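# Priors for the log-binomial two-group model: a Normal prior on the log
# risk ratio (elicited from a published estimate or weakly informative)
# and a Student-t prior on the intercept (log baseline risk).

.z975 <- 1.959964  # fixed for reproducible CI <-> sigma conversions

#' Prior on the log risk ratio
#'
#' @param mu Mean of the Normal prior on log-RR.
#' @param sigma Standard deviation of that prior (`Inf` gives a truly
#'   improper flat prior on log-RR).
#' @param intercept_df,intercept_location,intercept_scale Student-t prior
#'   on the model intercept (log risk in the before epoch). A `NULL`
#'   location is resolved at fit time to the log pooled risk of the data.
#' @param flavour `"informative"` (elicited from an external estimate),
#'   `"weakly_informative"` (the default sensitivity prior) or `"flat"`.
#' @return Object of class `rr_prior`.
#' @export
rr_prior <- function(mu, sigma, intercept_df = 3, intercept_location = NULL,
                     intercept_scale = 2.5,
                     flavour = c("informative", "weakly_informative", "flat")) {
  flavour <- match.arg(flavour)
  if (!is.infinite(sigma) && sigma <= 0) stop("sigma must be > 0")
  if (intercept_scale <= 0) stop("intercept_scale must be > 0")
  if (intercept_df <= 0) stop("intercept_df must be > 0")
  structure(list(mu = mu, sigma = sigma, intercept_df = intercept_df,
                 intercept_location = intercept_location,
                 intercept_scale = intercept_scale, flavour = flavour),
            class = "rr_prior")
}

#' @export
print.rr_prior <- function(x, ...) {
  cat(sprintf("%s prior: log-RR ~ Normal(%.4f, %.4f); intercept ~ Student-t(df=%g, %s, %.2f)\n",
              x$flavour, x$mu, x$sigma, x$intercept_df,
              if (is.null(x$intercept_location)) "log pooled risk"
              else sprintf("%.3f", x$intercept_location),
              x$intercept_scale))
  invisible(x)
}

#' Weakly informative default prior
#'
#' The sensitivity-analysis prior: log-RR ~ Normal(0, 10) with a
#' Student-t(3) intercept centred at the log pooled risk, scale 2.5.
#'
#' @inheritParams rr_prior
#' @return An [rr_prior()].
#' @export
weakly_informative_prior <- function(intercept_df = 3,
                                     intercept_location = NULL,
                                     intercept_scale = 2.5) {
  rr_prior(0, 10, intercept_df, intercept_location, intercept_scale,
           flavour = "weakly_informative")
}

#' Elicit a Normal log-RR prior from a published estimate
#'
#' Converts a published risk ratio with a 95% confidence interval into the
#' Normal prior on the log risk ratio it implies: `mu = log(rr_point)` and
#' `sigma` set so that `exp(mu +/- 1.959964 * sigma)` recovers the
#' interval.
#'
#' @param rr_point Published point estimate (risk ratio).
#' @param ci_low,ci_high Its 95% confidence interval.
#' @inheritParams rr_prior
#' @return An [rr_prior()] with `flavour = "informative"`.
#' @export
elicit_normal_prior <- function(rr_point, ci_low, ci_high, intercept_df = 3,
                                intercept_location = NULL,
                                intercept_scale = 2.5) {
  if (any(c(rr_point, ci_low, ci_high) <= 0)) {
    stop("risk ratio and interval must be strictly positive")
  }
  if (!(ci_low <= rr_point && rr_point <= ci_high)) {
    stop("need ci_low <= rr_point <= ci_high")
  }
  rr_prior(mu = log(rr_point),
           sigma = (log(ci_high) - log(ci_low)) / (2 * .z975),
           intercept_df = intercept_df,
           intercept_location = intercept_location,
           intercept_scale = intercept_scale,
           flavour = "informative")
}
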