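# In-code fixtures: small hand-built cohorts and record builders shared
# across test files. All data are constructed programmatically.

# a block of n identical rows, with per-field overrides
make_records <- function(n = 1, ...) {
  base <- data.frame(
    record_id = paste0("R", seq_len(n)),
    site = "SGH",
    birth_date = as.Date("2019-06-15"),
    gestational_age_days = 280L,
    plurality = 1L,
    presentation_at_birth = "cephalic",
    antenatally_diagnosed_breech = FALSE,
    onset = "spontaneous_labour",
    planned_cesarean_for_breech = FALSE,
    mode_of_birth = "vaginal_vertex_spontaneous",
    apgar5 = 9L,
    nnu_admission = FALSE,
    hie = FALSE,
    perinatal_death = FALSE,
    congenital_anomaly = FALSE,
    maternal_age_years = 33,
    bmi = 25,
    parous = FALSE,
    ethnicity = "Caucasian",
    imd_quintile = 3L,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (f in names(over)) base[[f]] <- over[[f]]
  base
}

# breech block: k_undiag undiagnosed (labour onset), the rest antenatally
# diagnosed, with a given mode split among the diagnosed
make_breech_block <- function(n, k_undiag, date, modes_diagnosed) {
  undiag <- make_records(k_undiag,
    presentation_at_birth = "breech",
    antenatally_diagnosed_breech = FALSE,
    onset = "spontaneous_labour",
    mode_of_birth = "emergency_cesarean",
    birth_date = date)
  diag <- make_records(n - k_undiag,
    presentation_at_birth = "breech",
    antenatally_diagnosed_breech = TRUE,
    onset = "induction",
    mode_of_birth = modes_diagnosed,
    birth_date = date)
  diag$onset[diag$mode_of_birth == "elective_cesarean"] <- "planned_cesarean"
  rbind(undiag, diag)
}

# rep() a mode table (named counts) into a vector of length sum(counts)
rep_modes <- function(counts) rep(names(counts), counts)

# Cohort whose marginal counts match the published study tables for the
# routine-scan hospital: per-epoch totals, breech totals, undiagnosed
# counts, and mode-of-birth splits among breech. Flags mark no record as
# protocol-excluded so table denominators are the full breech counts.
make_study_fixture_sgh <- function() {
  d_before <- as.Date("2018-06-01"); d_after <- as.Date("2020-06-01")
  # before: 578 breech of 16,777; 82 undiagnosed; diagnosed modes from the
  # breech mode-of-birth table (elective 351, emergency 96 of 178 after
  # the 82 undiagnosed emergencies, spontaneous 32, extraction 13, forceps 4)
  modes_b <- rep_modes(c(elective_cesarean = 351, emergency_cesarean = 96,
                         vaginal_breech_spontaneous = 32,
                         vaginal_breech_extraction = 13,
                         vaginal_breech_forceps = 4))
  breech_b <- make_breech_block(578, 82, d_before, modes_b)
  ceph_b <- make_records(16777 - 578, birth_date = d_before)
  # after: 251 breech of 7,351; 7 undiagnosed; elective 193, emergency 36,
  # spontaneous 11, extraction 2, forceps 2
  modes_a <- rep_modes(c(elective_cesarean = 193, emergency_cesarean = 36,
                         vaginal_breech_spontaneous = 11,
                         vaginal_breech_extraction = 2,
                         vaginal_breech_forceps = 2))
  breech_a <- make_breech_block(251, 7, d_after, modes_a)
  ceph_a <- make_records(7351 - 251, birth_date = d_after)
  out <- rbind(breech_b, ceph_b, breech_a, ceph_a)
  out$record_id <- paste0("S", seq_len(nrow(out)))
  as_birth_records(out)
}

# breech-only records for the point-of-care hospital: 27/167 undiagnosed
# before, 5/142 after
make_study_fixture_nnuh_breech <- function() {
  d_before <- as.Date("2015-06-01"); d_after <- as.Date("2021-03-01")
  b <- make_breech_block(167, 27, d_before,
                         rep("elective_cesarean", 140))
  a <- make_breech_block(142, 5, d_after,
                         rep("elective_cesarean", 137))
  out <- rbind(b, a)
  out$site <- "NNUH"
  out$record_id <- paste0("N", seq_len(nrow(out)))
  as_birth_records(out)
}

sgh_cut <- as.Date("2020-01-01")
nnuh_cut <- as.Date("2020-11-01")
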