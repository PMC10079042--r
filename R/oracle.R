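#' Grid-integration oracle for the log-binomial posterior
#'
#' Deterministic brute-force validation of the sampler: evaluates the
#' unnormalised posterior of (alpha, beta) on a fine two-dimensional grid
#' over the constrained support (alpha <= 0, alpha + beta <= 0),
#' normalises by quadrature, and extracts the marginal posterior of the
#' log risk ratio: median and equal-tailed 95% interval of `exp(beta)`
#' (interpolated from the marginal CDF) and the exact grid probability
#' P(beta < 0).
#'
#' @param summary A [cohort_summary()].
#' @param prior An [rr_prior()].
#' @param n_grid Grid points per dimension.
#' @return A list with `rr_median`, `cri_low`, `cri_high`,
#'   `prob_reduction`, and the marginal grid (`beta`, `density`).
#' @export
grid_posterior_oracle <- function(summary, prior, n_grid = 400) {
  stopifnot(inherits(summary, "cohort_summary"), inherits(prior, "rr_prior"))
  prior <- .resolve_prior(prior, summary)
  a <- summary$events[1]; n1 <- summary$totals[1]
  c2 <- summary$events[2]; n2 <- summary$totals[2]

  # bounds from a precision-weighted normal approximation of the posterior
  # (likelihood moments combined with the prior), so the grid stays fine
  # whether the prior is tight or effectively flat
  a_hat <- log((a + 0.5) / (n1 + 1)); se_a <- sqrt(1 / (a + 0.5))
  b_hat <- log((c2 + 0.5) / (n2 + 1)) - a_hat
  se_b <- sqrt(1 / (a + 0.5) + 1 / (c2 + 0.5))
  prec_a <- 1 / se_a^2 + 1 / prior$intercept_scale^2
  ctr_a <- (a_hat / se_a^2 + prior$intercept_location / prior$intercept_scale^2) /
    prec_a
  sd_a <- 1 / sqrt(prec_a)
  prec_b <- 1 / se_b^2 + if (is.infinite(prior$sigma)) 0 else 1 / prior$sigma^2
  ctr_b <- (b_hat / se_b^2 +
              if (is.infinite(prior$sigma)) 0 else prior$mu / prior$sigma^2) /
    prec_b
  sd_b <- 1 / sqrt(prec_b)
  alpha <- seq(ctr_a - 12 * sd_a, min(0, ctr_a + 12 * sd_a),
               length.out = n_grid)
  beta <- seq(ctr_b - 12 * sd_b, ctr_b + 12 * sd_b, length.out = n_grid)

  lp <- outer(alpha, beta, .log_post, a = a, n1 = n1, c2 = c2, n2 = n2,
              prior = prior)
  mx <- max(lp)
  if (!is.finite(mx)) {
    stop("grid mass underflow: posterior is zero everywhere on the grid; ",
         "widen or rescale the grid")
  }
  w <- exp(lp - mx)
  marg <- colSums(w)
  total <- sum(marg)
  if (!is.finite(total) || total <= 0) {
    stop("grid mass underflow: try a wider or rescaled grid")
  }
  marg <- marg / total
  cdf <- cumsum(marg)

  qtl <- function(p) {
    i <- findInterval(p, cdf) + 1L
    i <- min(max(i, 2L), length(beta))
    # linear interpolation within the bracketing grid cell
    c0 <- cdf[i - 1L]; c1 <- cdf[i]
    beta[i - 1L] + (beta[i] - beta[i - 1L]) * (p - c0) / max(c1 - c0, 1e-300)
  }
  p_below0 <- if (beta[1] >= 0) 0 else if (beta[n_grid] <= 0) 1 else {
    i <- findInterval(0, beta)
    cdf[i] + (0 - beta[i]) / (beta[i + 1] - beta[i]) * marg[i + 1]
  }
  list(rr_median = exp(qtl(0.5)),
       cri_low = exp(qtl(0.025)),
       cri_high = exp(qtl(0.975)),
       prob_reduction = p_below0,
       grid = data.frame(beta = beta, density = marg))
}
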