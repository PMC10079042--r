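# Seeded synthetic birth cohorts with the two-epoch structure the analysis
# assumes: a ~3-4% term breech rate, an epoch-dependent undiagnosed
# fraction, and rare adverse outcomes whose risk is elevated when breech is
# missed antenatally.

#' Simulation configuration
#'
#' Defaults reflect the screening-policy setting the pipeline targets: a
#' 3.4% breech rate at term, an undiagnosed fraction falling from 14.2% to
#' 2.8% of breech births across the policy change, and rare neonatal
#' outcomes whose conditional risks are simulation knobs rather than
#' estimates. Demographics are cosmetic and never drive outcome risk (the
#' analysis fits unadjusted two-group models).
#'
#' @param n_before,n_after Births per epoch.
#' @param months_before,months_after Calendar span of each epoch in months.
#' @param cut_date Policy change date (first day of the "after" epoch).
#' @param p_breech Probability of breech presentation at birth.
#' @param p_undiagnosed_given_breech Pair `(before, after)`: probability a
#'   breech is undiagnosed antenatally in each epoch.
#' @param p_multiple,p_preterm,p_anomaly Exclusion-criterion probabilities
#'   (twin pregnancy, birth before 37+0 weeks, congenital anomaly).
#' @param p_planned_cs_given_diagnosed Probability an antenatally diagnosed
#'   breech carries the planned-cesarean-for-breech flag, i.e. belongs to
#'   the subset a site's protocol removes from non-neonatal outcome
#'   denominators. The default of 0 keeps every breech birth in the
#'   denominators, matching study tables in which elective cesareans for
#'   diagnosed breech remain part of the breech totals; raise it to
#'   exercise [apply_planned_cs_rule()].
#' @param outcome_risks Named list mapping outcome name to a
#'   `(diagnosed, undiagnosed)` risk pair among breech births.
#' @param baseline_risks Named vector of outcome risks among non-breech
#'   births (keeps whole-cohort tables populated).
#' @param p_missing_apgar Probability the 5-minute Apgar score is missing.
#' @param site Site label stamped on every record.
#' @param seed Integer seed; one pseudo-random stream per cohort.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_before = 5000, n_after = 5000,
                       months_before = 12, months_after = 12,
                       cut_date = as.Date("2020-11-01"),
                       p_breech = 0.034,
                       p_undiagnosed_given_breech = c(before = 0.142, after = 0.028),
                       p_multiple = 0.015, p_preterm = 0.07, p_anomaly = 0.02,
                       p_planned_cs_given_diagnosed = 0,
                       outcome_risks = list(
                         apgar_lt7 = c(diagnosed = 0.008, undiagnosed = 0.08),
                         nnu_admission = c(diagnosed = 0.03, undiagnosed = 0.12),
                         hie = c(diagnosed = 0.002, undiagnosed = 0.02),
                         perinatal_death = c(diagnosed = 0.002, undiagnosed = 0.015)),
                       baseline_risks = c(apgar_lt7 = 0.004, nnu_admission = 0.01,
                                          hie = 0.0005, perinatal_death = 0.0005),
                       p_missing_apgar = 0, site = "SGH", seed = 1L) {
  probs <- c(p_breech, p_undiagnosed_given_breech, p_multiple, p_preterm,
             p_anomaly, p_planned_cs_given_diagnosed, p_missing_apgar,
             unlist(outcome_risks), baseline_risks)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (n_before <= 0 || n_after <= 0) stop("n_before and n_after must be positive")
  if (length(p_undiagnosed_given_breech) != 2) {
    stop("p_undiagnosed_given_breech must be a (before, after) pair")
  }
  structure(list(n_before = as.integer(n_before), n_after = as.integer(n_after),
                 months_before = as.integer(months_before),
                 months_after = as.integer(months_after),
                 cut_date = as.Date(cut_date), p_breech = p_breech,
                 p_undiagnosed_given_breech = p_undiagnosed_given_breech,
                 p_multiple = p_multiple, p_preterm = p_preterm,
                 p_anomaly = p_anomaly,
                 p_planned_cs_given_diagnosed = p_planned_cs_given_diagnosed,
                 outcome_risks = outcome_risks, baseline_risks = baseline_risks,
                 p_missing_apgar = p_missing_apgar, site = site,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run expr with a private, seeded RNG stream; global .Random.seed untouched
with_sim_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.month_seq <- function(from, n_months) {
  seq(from, by = "month", length.out = n_months + 1)
}

#' Generate a synthetic two-epoch birth cohort
#'
#' Draws `n_before + n_after` births with uniform birth dates over each
#' epoch's month span, Bernoulli breech status, epoch-dependent antenatal
#' diagnosis, and adverse outcomes conditional on (breech, diagnosed).
#' Alongside the records it returns a `truth` tally of every planted count,
#' computed by direct counting over the simulated vectors — independent of
#' the pipeline's own aggregation code — so generator-to-pipeline agreement
#' is a meaningful test. Identical seeds give identical cohorts.
#'
#' @param config A [sim_config()].
#' @return List with `records` (validated cohort data frame) and `truth`
#'   (list of planted tallies; see Details).
#' @details `truth` contains, for each epoch, post-exclusion birth and
#'   breech totals, undiagnosed-breech counts, planned-cesarean-for-breech
#'   counts, breech denominators with the planned-cesarean rule applied,
#'   and per-outcome event counts among breech births (neonatal outcomes
#'   keep planned cesareans; `undiagnosed_breech` drops them), plus the
#'   exclusion tally by reason.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_before + cfg$n_after
  after <- rep(c(FALSE, TRUE), c(cfg$n_before, cfg$n_after))

  start_before <- seq(cfg$cut_date, by = paste(-cfg$months_before, "month"),
                      length.out = 2)[2]
  end_after <- seq(cfg$cut_date, by = paste(cfg$months_after, "month"),
                   length.out = 2)[2]
  bd <- as.Date(integer(n), origin = "1970-01-01")
  span_b <- as.integer(cfg$cut_date - start_before)
  span_a <- as.integer(end_after - cfg$cut_date)
  bd[!after] <- start_before + floor(stats::runif(cfg$n_before) * span_b)
  bd[after] <- cfg$cut_date + floor(stats::runif(cfg$n_after) * span_a)

  plurality <- 1L + stats::rbinom(n, 1L, cfg$p_multiple)
  preterm <- stats::runif(n) < cfg$p_preterm
  ga <- ifelse(preterm, 196L + floor(stats::runif(n) * 63),
               259L + floor(stats::runif(n) * 35))
  anomaly <- stats::runif(n) < cfg$p_anomaly
  breech <- stats::runif(n) < cfg$p_breech

  p_undiag <- ifelse(after, cfg$p_undiagnosed_given_breech[2],
                     cfg$p_undiagnosed_given_breech[1])
  undiag <- breech & (stats::runif(n) < p_undiag)
  diagnosed_breech <- breech & !undiag

  planned_cs <- diagnosed_breech & (stats::runif(n) < cfg$p_planned_cs_given_diagnosed)
  # diagnosed breech mostly reaches birth by elective cesarean whether or
  # not the protocol flag is set
  elective_breech <- planned_cs |
    (diagnosed_breech & !planned_cs & stats::runif(n) < 0.75)

  onset <- character(n)
  labourish <- c("spontaneous_labour", "prelabour_ROM", "induction")
  u <- stats::runif(n)
  onset[undiag] <- labourish[1 + findInterval(u[undiag], c(0.6, 0.8))]
  onset[elective_breech] <- "planned_cesarean"
  rest_breech <- diagnosed_breech & !elective_breech
  onset[rest_breech] <- labourish[1 + findInterval(u[rest_breech], c(0.5, 0.7))]
  onset[!breech] <- c(labourish, "planned_cesarean")[
    1 + findInterval(u[!breech], c(0.55, 0.70, 0.95))]

  mode <- character(n)
  v <- stats::runif(n)
  mode[elective_breech] <- "elective_cesarean"
  mode[rest_breech] <- c("emergency_cesarean", "vaginal_breech_spontaneous",
                         "vaginal_breech_extraction")[
    1 + findInterval(v[rest_breech], c(0.8, 0.95))]
  mode[undiag] <- c("emergency_cesarean", "vaginal_breech_spontaneous",
                    "vaginal_breech_extraction", "vaginal_breech_forceps")[
    1 + findInterval(v[undiag], c(0.6, 0.85, 0.95))]
  nb <- !breech
  ceph_planned <- nb & onset == "planned_cesarean"
  mode[ceph_planned] <- "elective_cesarean"
  ceph_lab <- nb & onset != "planned_cesarean"
  mode[ceph_lab] <- c("vaginal_vertex_spontaneous", "vaginal_vertex_operative",
                      "emergency_cesarean")[
    1 + findInterval(v[ceph_lab], c(0.68, 0.87))]

  draw_outcome <- function(nm) {
    risk <- rep(cfg$baseline_risks[[nm]], n)
    risk[diagnosed_breech] <- cfg$outcome_risks[[nm]][1]
    risk[undiag] <- cfg$outcome_risks[[nm]][2]
    stats::runif(n) < risk
  }
  apgar_low <- draw_outcome("apgar_lt7")
  nnu <- draw_outcome("nnu_admission")
  hie <- draw_outcome("hie")
  death <- draw_outcome("perinatal_death")

  apgar5 <- ifelse(apgar_low, floor(stats::runif(n) * 7),
                   7L + floor(stats::runif(n) * 4))
  apgar5[stats::runif(n) < cfg$p_missing_apgar] <- NA_integer_

  eth_levels <- c("Caucasian", "Black", "Asian", "Mixed", "Other", "Not stated")
  records <- data.frame(
    record_id = sprintf("B%06d", seq_len(n)),
    site = cfg$site,
    birth_date = bd,
    gestational_age_days = as.integer(ga),
    plurality = plurality,
    presentation_at_birth = ifelse(breech, "breech", "cephalic"),
    antenatally_diagnosed_breech = diagnosed_breech,
    onset = onset,
    planned_cesarean_for_breech = planned_cs,
    mode_of_birth = mode,
    apgar5 = as.integer(apgar5),
    nnu_admission = nnu,
    hie = hie,
    perinatal_death = death,
    congenital_anomaly = anomaly,
    maternal_age_years = round(stats::rnorm(n, 33 + 0.5 * after, 5.2), 1),
    bmi = round(stats::rnorm(n, 25.6, 5.3), 1),
    parous = stats::runif(n) < 0.496,
    ethnicity = eth_levels[1 + floor(stats::runif(n) * length(eth_levels))],
    imd_quintile = 1L + floor(stats::runif(n) * 5),
    stringsAsFactors = FALSE
  )

  # truth tally via direct counting, mirroring the exclusion and
  # planned-cesarean rules but coded independently of the pipeline
  excl_reason <- rep(NA_character_, n)
  excl_reason[plurality > 1] <- "multiple_pregnancy"
  excl_reason[is.na(excl_reason) & ga < 259] <- "preterm"
  excl_reason[is.na(excl_reason) & anomaly] <- "congenital_anomaly"
  keep <- is.na(excl_reason)

  cnt <- function(x) c(before = sum(x & keep & !after), after = sum(x & keep & after))
  non_cs <- !planned_cs
  truth <- list(
    epochs = c("before", "after"),
    exclusions = c(multiple_pregnancy = sum(excl_reason == "multiple_pregnancy",
                                            na.rm = TRUE),
                   preterm = sum(excl_reason == "preterm", na.rm = TRUE),
                   congenital_anomaly = sum(excl_reason == "congenital_anomaly",
                                            na.rm = TRUE)),
    n_eligible = cnt(rep(TRUE, n)),
    n_breech = cnt(breech),
    n_breech_non_cs = cnt(breech & non_cs),
    planned_cs_breech = cnt(planned_cs),
    n_undiagnosed = cnt(undiag & non_cs),
    outcomes = list(
      apgar_lt7 = cnt(breech & apgar_low & !is.na(apgar5)),
      nnu_admission = cnt(breech & nnu),
      hie = cnt(breech & hie),
      perinatal_death = cnt(breech & death)
    )
  )
  list(records = as_birth_records(records), truth = truth)
}

#' Realised risk ratio from a truth tally
#'
#' Ground truth for parameter-recovery tests: the after/before risk ratio
#' implied by the planted counts of a generated cohort.
#'
#' @param truth The `truth` element of [generate_cohort()].
#' @param outcome_name `"undiagnosed_breech"` or a registered neonatal
#'   outcome name.
#' @return The realised risk ratio (after risk / before risk).
#' @export
planted_rr <- function(truth, outcome_name) {
  if (outcome_name == "undiagnosed_breech") {
    ev <- truth$n_undiagnosed
    tot <- truth$n_breech_non_cs
  } else {
    if (!outcome_name %in% names(truth$outcomes)) {
      stop("unknown outcome '", outcome_name, "' in truth tally")
    }
    ev <- truth$outcomes[[outcome_name]]
    tot <- truth$n_breech
  }
  if (ev[["before"]] == 0) {
    stop("risk ratio undefined: zero events in the 'before' epoch")
  }
  (ev[["after"]] / tot[["after"]]) / (ev[["before"]] / tot[["before"]])
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: generates a cohort and writes the records as CSV
#' and the truth tally as JSON next to it.
#'
#' @param config A [sim_config()].
#' @param csv_path Output CSV path for the records.
#' @param truth_path Output JSON path for the truth tally (default:
#'   `csv_path` with a `.truth.json` suffix).
#' @return The [generate_cohort()] result, invisibly.
#' @export
simulate_cohort <- function(config, csv_path,
                            truth_path = sub("\\.csv$", ".truth.json", csv_path)) {
  sim <- generate_cohort(config)
  write_birth_records(sim$records, csv_path)
  writeLines(jsonlite::toJSON(sim$truth, auto_unbox = FALSE, digits = NA,
                              pretty = TRUE), truth_path)
  invisible(sim)
}
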