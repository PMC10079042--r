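test_that("single-event correction touches only zero cells and flags itself", {
  s1 <- zero_event_correction(cohort_summary("x", c(0, 3), c(167, 142)))
  expect_equal(s1$events, c(1L, 3L))
  expect_equal(s1$totals, c(167L, 142L))
  expect_true(attr(s1, "corrected"))

  s2 <- zero_event_correction(cohort_summary("x", c(5, 7), c(100, 100)))
  expect_equal(s2$events, c(5L, 7L))
  expect_false(attr(s2, "corrected"))

  s3 <- zero_event_correction(cohort_summary("x", c(0, 0), c(50, 60)))
  expect_equal(s3$events, c(1L, 1L))
})

test_that("the sampler is deterministic given summary, prior and seed", {
  s <- cohort_summary("u", c(27, 5), c(167, 142))
  m <- mcmc_config(seed = 5)
  f1 <- fit_logbinomial(s, weakly_informative_prior(), m)
  f2 <- fit_logbinomial(s, weakly_informative_prior(), m)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$rr_median, f2$rr_median)
  expect_identical(f1$prob_reduction, f2$prob_reduction)
  f3 <- fit_logbinomial(s, weakly_informative_prior(), mcmc_config(seed = 6))
  expect_false(identical(f1$rr_median, f3$rr_median))
})

test_that("fits are well-behaved: ordering, diagnostics, chain mixing", {
  s <- cohort_summary("u", c(27, 5), c(167, 142))
  f <- fit_logbinomial(s, weakly_informative_prior(), mcmc_config(seed = 2))
  expect_lte(f$cri_low, f$rr_median)
  expect_lte(f$rr_median, f$cri_high)
  expect_gte(f$prob_reduction, 0); expect_lte(f$prob_reduction, 1)
  expect_lt(f$rhat, 1.05)
  expect_gte(f$accept_rate, 0.1); expect_lte(f$accept_rate, 0.6)
  expect_equal(nrow(f$samples), 2 * 1500)
  # log-link support: every draw keeps both fitted risks below 1
  expect_true(all(f$samples$alpha <= 0))
  expect_true(all(f$samples$alpha + f$samples$beta <= 0))
})

test_that("a near-degenerate prior pins the risk ratio at its mean", {
  s <- cohort_summary("u", c(30, 5), c(150, 150))
  f <- suppressWarnings(
    fit_logbinomial(s, rr_prior(0, 1e-6), mcmc_config(seed = 3)))
  expect_lte(abs(f$rr_median - 1.0), 1e-3)
})

test_that("with large counts the posterior collapses onto the crude risk ratio", {
  s <- cohort_summary("u", c(1000, 500), c(10000, 10000))
  f <- fit_logbinomial(s, weakly_informative_prior(), mcmc_config(seed = 8))
  expect_lte(abs(f$rr_median - 0.5), 0.02)
  o <- grid_posterior_oracle(s, weakly_informative_prior())
  expect_lte(abs(o$rr_median - 0.5), 0.005)
})

test_that("the grid oracle is symmetric when the data are", {
  s <- cohort_summary("u", c(10, 10), c(100, 100))
  o <- grid_posterior_oracle(s, weakly_informative_prior())
  expect_lte(abs(o$rr_median - 1.0), 0.02)
  # not exactly one half: the intercept prior sits on the before-epoch
  # risk only, so the two groups are not perfectly exchangeable
  expect_lte(abs(o$prob_reduction - 0.5), 0.02)
})

test_that("sampler and oracle agree on a spot-check fit", {
  s <- cohort_summary("u", c(12, 4), c(80, 90))
  pr <- rr_prior(-0.5, 0.6)
  f <- fit_logbinomial(s, pr, mcmc_config(seed = 9))
  o <- grid_posterior_oracle(s, pr)
  expect_lte(abs(f$rr_median - o$rr_median), 0.03)
  expect_lte(abs(f$cri_low - o$cri_low), 0.05)
  expect_lte(abs(f$cri_high - o$cri_high), 0.08)
})

test_that("normal-density reduction probabilities track the empirical tail", {
  # exactly symmetric draws about zero
  x <- c(rnorm(200), -rnorm(200))
  x <- c(x, -x)
  expect_equal(posterior_prob_reduction(x), 0.5)
  expect_error(posterior_prob_reduction(rnorm(50)), "at least 100")
  expect_message(p <- posterior_prob_reduction(rep(-0.2, 200)), "degenerate")
  expect_equal(p, 1)

  set.seed(44)
  for (i in 1:20) {
    a <- rbinom(1, 200, runif(1, 0.05, 0.3)) + 1
    c2 <- rbinom(1, 200, runif(1, 0.05, 0.3)) + 1
    f <- fit_logbinomial(cohort_summary("u", c(a, c2), c(200, 200)),
                         weakly_informative_prior(), mcmc_config(seed = i))
    expect_lte(abs(f$prob_reduction - mean(f$samples$beta < 0)), 0.02,
               label = sprintf("normal-fit vs empirical tail gap (case %d)", i))
  }
})

test_that("reduction probability decreases as the prior mean rises", {
  s <- cohort_summary("u", c(20, 10), c(150, 150))
  probs <- vapply(c(-1, 0, 1), function(mu) {
    fit_logbinomial(s, rr_prior(mu, 0.5), mcmc_config(seed = 13))$prob_reduction
  }, 0)
  expect_true(all(diff(probs) < 0))
})

test_that("informative priors pull the flat-prior estimate toward the prior mean", {
  set.seed(77)
  for (i in 1:5) {
    a <- rbinom(1, 150, 0.2) + 1; c2 <- rbinom(1, 150, 0.1) + 1
    s <- cohort_summary("u", c(a, c2), c(150, 150))
    crude <- log((c2 / 150) / (a / 150))
    mu <- crude + sample(c(-1, 1), 1) * runif(1, 0.5, 1)
    flat <- fit_logbinomial(s, weakly_informative_prior(), mcmc_config(seed = i))
    inf <- fit_logbinomial(s, rr_prior(mu, 0.3), mcmc_config(seed = i))
    expect_equal(sign(log(inf$rr_median) - log(flat$rr_median)),
                 sign(mu - crude),
                 label = sprintf("shrinkage direction (case %d)", i))
  }
})

test_that("sensitivity_flat is the weakly-informative refit", {
  s <- cohort_summary("u", c(27, 5), c(167, 142))
  f1 <- sensitivity_flat(s, mcmc_config(seed = 4))
  f2 <- fit_logbinomial(s, weakly_informative_prior(), mcmc_config(seed = 4))
  expect_identical(f1$rr_median, f2$rr_median)
  expect_equal(f1$prior$flavour, "weakly_informative")
})

test_that("an improper flat prior is available and close to the weak default", {
  s <- cohort_summary("u", c(27, 5), c(167, 142))
  f <- fit_logbinomial(s, rr_prior(0, Inf, flavour = "flat"),
                       mcmc_config(seed = 10))
  o <- grid_posterior_oracle(s, rr_prior(0, Inf, flavour = "flat"))
  expect_lte(abs(f$rr_median - o$rr_median), 0.03)
})
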