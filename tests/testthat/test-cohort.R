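test_that("a well-formed file round-trips through write and read", {
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- make_records(3, record_id = c("a", "b", "c"),
                       apgar5 = c(9L, 7L, NA))
  write_birth_records(as_birth_records(recs), path)
  back <- read_birth_records(path)
  expect_equal(nrow(back), 3)
  expect_equal(back, as_birth_records(recs))
})

test_that("a generated cohort survives a write/read round-trip unchanged", {
  sim <- generate_cohort(sim_config(n_before = 500, n_after = 500, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_birth_records(sim$records, path)
  expect_equal(read_birth_records(path), sim$records)
})

test_that("validation rejects bad rows naming row and field", {
  bad <- make_records(2)
  bad$apgar5[2] <- 12L
  expect_error(as_birth_records(bad), "row 2: apgar5")
  bad2 <- make_records(1, plurality = 0L)
  expect_error(as_birth_records(bad2), "plurality")
  # flag without breech presentation violates a record invariant
  bad3 <- make_records(1, planned_cesarean_for_breech = TRUE)
  expect_error(as_birth_records(bad3), "planned_cesarean_for_breech")
  # schema error: a required column is absent
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_records(2); df$apgar5 <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_birth_records(path), "missing required column.*apgar5")
})

test_that("exclusions use the 37-week boundary and tally every removal", {
  recs <- as_birth_records(rbind(
    make_records(1, record_id = "term", gestational_age_days = 259L),
    make_records(1, record_id = "preterm", gestational_age_days = 258L),
    make_records(1, record_id = "twin", plurality = 2L),
    make_records(1, record_id = "anomaly", congenital_anomaly = TRUE)
  ))
  ex <- apply_exclusions(recs)
  expect_equal(ex$kept$record_id, "term")
  expect_equal(ex$excluded[["preterm"]], 1L)
  expect_equal(ex$excluded[["multiple_pregnancy"]], 1L)
  expect_equal(ex$excluded[["congenital_anomaly"]], 1L)
})

test_that("exclusion counts are conserved and the filter is idempotent", {
  for (seed in 1:3) {
    sim <- generate_cohort(sim_config(n_before = 800, n_after = 800,
                                      seed = seed))
    ex <- apply_exclusions(sim$records)
    expect_equal(nrow(ex$kept) + sum(ex$excluded), nrow(sim$records))
    expect_equal(ex$excluded, sim$truth$exclusions)
    again <- apply_exclusions(ex$kept)
    expect_equal(again$kept, ex$kept)
    expect_equal(sum(again$excluded), 0L)
  }
})

test_that("planned-cesarean rule spares neonatal outcomes and removes flagged records otherwise", {
  flagged <- make_records(2, presentation_at_birth = "breech",
                          antenatally_diagnosed_breech = TRUE,
                          onset = "planned_cesarean",
                          planned_cesarean_for_breech = TRUE,
                          mode_of_birth = "elective_cesarean")
  recs <- as_birth_records(rbind(make_records(3), flagged))
  expect_identical(apply_planned_cs_rule(recs, "apgar_lt7"), recs)
  expect_equal(nrow(apply_planned_cs_rule(recs, "elective_cesarean")), 3)
  expect_error(apply_planned_cs_rule(recs, "not_an_outcome"), "unknown outcome")
})

test_that("undiagnosed breech means no antenatal diagnosis and discovery at labour, membrane rupture or induction", {
  br <- function(...) as_birth_records(make_records(1,
    presentation_at_birth = "breech", mode_of_birth = "emergency_cesarean",
    ...))
  expect_true(classify_undiagnosed_breech(
    br(antenatally_diagnosed_breech = FALSE, onset = "spontaneous_labour")))
  expect_true(classify_undiagnosed_breech(
    br(antenatally_diagnosed_breech = FALSE, onset = "induction")))
  expect_true(classify_undiagnosed_breech(
    br(antenatally_diagnosed_breech = FALSE, onset = "prelabour_ROM")))
  expect_false(classify_undiagnosed_breech(
    br(antenatally_diagnosed_breech = TRUE, onset = "planned_cesarean")))
  expect_false(classify_undiagnosed_breech(
    br(antenatally_diagnosed_breech = TRUE, onset = "spontaneous_labour")))
  expect_error(classify_undiagnosed_breech(as_birth_records(make_records(1))),
               "non-breech")
})

test_that("summaries report exact percentages and fail on empty epochs", {
  recs <- make_study_fixture_nnuh_breech()
  ep <- epoch_spec(nnuh_cut)
  s <- summarise_outcome(recs, ep, "undiagnosed_breech", "breech_births")
  expect_equal(s$events, c(27L, 5L))
  expect_equal(s$totals, c(167L, 142L))
  expect_identical(proportions_pct(s), 100 * s$events / s$totals)
  # all records on one side of the cut
  expect_error(
    summarise_outcome(recs, epoch_spec("1990-01-01"), "undiagnosed_breech"),
    "epoch 'before'")
})

test_that("relabelling epochs relabels without touching the counts", {
  recs <- make_study_fixture_nnuh_breech()
  s1 <- summarise_outcome(recs, epoch_spec(nnuh_cut), "undiagnosed_breech")
  s2 <- summarise_outcome(recs, epoch_spec(nnuh_cut, "pre", "post"),
                          "undiagnosed_breech")
  expect_equal(s2$events, s1$events)
  expect_equal(s2$epoch_labels, c("pre", "post"))
})

test_that("records missing a required field drop out of that outcome only", {
  recs <- make_records(10, presentation_at_birth = "breech",
                       antenatally_diagnosed_breech = TRUE,
                       onset = "induction", mode_of_birth = "emergency_cesarean",
                       birth_date = rep(c(as.Date("2019-01-01"),
                                          as.Date("2021-01-01")), 5))
  recs$apgar5[1:2] <- NA
  recs <- as_birth_records(recs)
  ep <- epoch_spec("2020-01-01")
  s_apgar <- summarise_outcome(recs, ep, "apgar_lt7")
  expect_equal(sum(s_apgar$totals), 8)
  expect_equal(attr(s_apgar, "n_dropped_missing"), 2)
  s_undiag <- summarise_outcome(recs, ep, "undiagnosed_breech")
  expect_equal(sum(s_undiag$totals), 10)
})
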