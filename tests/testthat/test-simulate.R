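test_that("identical seeds give identical cohorts and the caller's RNG is untouched", {
  cfg <- sim_config(n_before = 400, n_after = 400, seed = 99)
  set.seed(123); before_draw <- runif(1)
  sim1 <- generate_cohort(cfg)
  sim2 <- generate_cohort(cfg)
  expect_identical(sim1$records, sim2$records)
  expect_identical(sim1$truth, sim2$truth)
  set.seed(123)
  expect_identical(runif(1), before_draw)
})

test_that("degenerate probabilities propagate exactly", {
  sim <- generate_cohort(sim_config(n_before = 300, n_after = 300,
                                    p_breech = 0, seed = 4))
  expect_equal(sum(sim$records$presentation_at_birth == "breech"), 0)
  expect_equal(unname(sim$truth$n_breech), c(0, 0))
  expect_error(sim_config(p_breech = 1.2), "probabilities")
  expect_error(sim_config(n_before = 0), "positive")
})

test_that("empirical breech fraction stays inside exact binomial 99% bounds", {
  n <- 20000
  sim <- generate_cohort(sim_config(n_before = n, n_after = 100, seed = 21))
  k <- sum(sim$records$presentation_at_birth == "breech" &
             sim$records$birth_date < sim_config()$cut_date)
  bounds <- qbinom(c(0.005, 0.995), n, 0.034)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("pipeline summaries agree exactly with the generator's truth tally", {
  ep <- epoch_spec("2020-11-01")
  for (seed in c(7, 8)) {
    # include planted protocol-excluded planned cesareans to exercise the rule
    sim <- generate_cohort(sim_config(n_before = 2000, n_after = 2000,
                                      p_planned_cs_given_diagnosed = 0.3,
                                      seed = seed))
    kept <- apply_exclusions(sim$records)$kept
    expect_equal(as.integer(table(assign_epoch(kept, ep))),
                 unname(sim$truth$n_eligible))

    su <- summarise_outcome(apply_planned_cs_rule(kept, "undiagnosed_breech"),
                            ep, "undiagnosed_breech")
    expect_equal(su$events, unname(sim$truth$n_undiagnosed))
    expect_equal(su$totals, unname(sim$truth$n_breech_non_cs))

    for (oc in c("apgar_lt7", "nnu_admission", "hie", "perinatal_death")) {
      so <- summarise_outcome(apply_planned_cs_rule(kept, oc), ep, oc)
      expect_equal(so$events, unname(sim$truth$outcomes[[oc]]),
                   label = paste(oc, "events"))
      expect_equal(so$totals, unname(sim$truth$n_breech),
                   label = paste(oc, "totals"))
    }
  }
})

test_that("undiagnosed fractions calibrate to the configured epoch rates", {
  # 200 replicates at 5,000 births per epoch; sample means within 3
  # Monte-Carlo standard errors of the configured 14.2% / 2.8%
  fr_b <- fr_a <- numeric(200)
  for (r in seq_len(200)) {
    sim <- generate_cohort(sim_config(n_before = 5000, n_after = 5000,
                                      seed = 5000 + r))
    fr_b[r] <- sim$truth$n_undiagnosed[["before"]] / sim$truth$n_breech[["before"]]
    fr_a[r] <- sim$truth$n_undiagnosed[["after"]] / sim$truth$n_breech[["after"]]
  }
  expect_lt(abs(mean(fr_b) - 0.142), 3 * sd(fr_b) / sqrt(200))
  expect_lt(abs(mean(fr_a) - 0.028), 3 * sd(fr_a) / sqrt(200))
})

test_that("planted risk ratios come straight from the truth tally", {
  truth <- list(n_undiagnosed = c(before = 82, after = 7),
                n_breech_non_cs = c(before = 578, after = 251),
                n_breech = c(before = 500, after = 250),
                outcomes = list(apgar_lt7 = c(before = 10, after = 5)))
  expect_equal(planted_rr(truth, "undiagnosed_breech"),
               (7 / 251) / (82 / 578), tolerance = 1e-12)
  expect_equal(round(planted_rr(truth, "undiagnosed_breech"), 4), 0.1966)
  expect_equal(planted_rr(truth, "apgar_lt7"), 1.0)
  truth$n_undiagnosed[["before"]] <- 0
  expect_error(planted_rr(truth, "undiagnosed_breech"), "undefined")
  expect_error(planted_rr(truth, "nope"), "unknown outcome")
})

test_that("simulate_cohort writes records and truth that reload consistently", {
  csv <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_cohort(sim_config(n_before = 200, n_after = 200, seed = 2),
                         csv)
  expect_equal(read_birth_records(csv), sim$records)
  truth <- jsonlite::fromJSON(sub("\\.csv$", ".truth.json", csv))
  expect_equal(unname(unlist(truth$n_breech)), unname(sim$truth$n_breech))
})
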