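#' @importFrom stats median quantile rnorm runif rbinom dnorm dt pnorm
#'   setNames complete.cases
#' @importFrom utils read.csv write.csv
NULL

# canonical column set and enum levels for a birth cohort
.sites <- c("SGH", "NNUH", "other")
.presentations <- c("cephalic", "breech", "other")
.onsets <- c("spontaneous_labour", "prelabour_ROM", "induction", "planned_cesarean")
.modes <- c("elective_cesarean", "emergency_cesarean",
            "vaginal_breech_spontaneous", "vaginal_breech_extraction",
            "vaginal_breech_forceps", "vaginal_vertex_spontaneous",
            "vaginal_vertex_operative")

#' Default column mapping for record-level birth data
#'
#' Maps canonical field names to the column headers expected in an input
#' CSV. Override entries to read files whose headers differ.
#'
#' @param ... named overrides, e.g. `apgar5 = "apgar_5min"`.
#' @return Named character vector mapping canonical field -> column name.
#' @export
birth_schema <- function(...) {
  fields <- c("record_id", "site", "birth_date", "gestational_age_days",
              "plurality", "presentation_at_birth",
              "antenatally_diagnosed_breech", "onset",
              "planned_cesarean_for_breech", "mode_of_birth", "apgar5",
              "nnu_admission", "hie", "perinatal_death", "congenital_anomaly",
              "maternal_age_years", "bmi", "parous", "ethnicity",
              "imd_quintile")
  map <- stats::setNames(fields, fields)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), fields)
    if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
    map[names(over)] <- over
  }
  map
}

.as_logical <- function(x) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

# validate a raw data frame of canonical columns; returns character vector of
# per-row problems ("row <i>: <field> <why>")
.validate_rows <- function(df) {
  probs <- character(0)
  note <- function(rows, field, why) {
    if (length(rows)) sprintf("row %d: %s %s", rows, field, why) else character(0)
  }
  chk_enum <- function(field, levels) {
    bad <- which(!is.na(df[[field]]) & !df[[field]] %in% levels)
    miss <- which(is.na(df[[field]]))
    c(note(bad, field, paste0("not one of {", paste(levels, collapse = ", "), "}")),
      note(miss, field, "is missing"))
  }
  chk_bool <- function(field) note(which(is.na(df[[field]])), field, "is not TRUE/FALSE")

  probs <- c(probs,
    note(which(is.na(df$birth_date)), "birth_date", "is not an ISO-8601 date"),
    note(which(is.na(df$gestational_age_days) | df$gestational_age_days < 0),
         "gestational_age_days", "must be a non-negative integer"),
    note(which(is.na(df$plurality) | df$plurality < 1),
         "plurality", "must be an integer >= 1"),
    chk_enum("site", .sites),
    chk_enum("presentation_at_birth", .presentations),
    chk_enum("onset", .onsets),
    chk_enum("mode_of_birth", .modes),
    chk_bool("antenatally_diagnosed_breech"),
    chk_bool("planned_cesarean_for_breech"),
    chk_bool("nnu_admission"), chk_bool("hie"), chk_bool("perinatal_death"),
    chk_bool("congenital_anomaly"),
    note(which(!is.na(df$apgar5) & (df$apgar5 < 0 | df$apgar5 > 10)),
         "apgar5", "must be in [0, 10] or missing"),
    note(which(!is.na(df$imd_quintile) &
                 (df$imd_quintile < 1 | df$imd_quintile > 5)),
         "imd_quintile", "must be in 1..5 or missing"),
    note(which(!is.na(df$planned_cesarean_for_breech) &
                 df$planned_cesarean_for_breech &
                 df$presentation_at_birth != "breech"),
         "planned_cesarean_for_breech",
         "is TRUE but presentation_at_birth is not breech"))
  probs
}

#' Read and validate record-level birth data
#'
#' Reads a delimited text file (CSV, UTF-8, header row, ISO-8601 dates) of
#' one row per birth and returns a validated cohort data frame with
#' canonical column names and types. Every row must satisfy the record
#' invariants (Apgar in 0-10, plurality >= 1, a planned cesarean for breech
#' implies breech presentation, ...); offending rows are reported with
#' their row number and field.
#'
#' @param path Path to the CSV file.
#' @param schema Column mapping from [birth_schema()].
#' @return A `data.frame` with one validated row per birth.
#' @export
read_birth_records <- function(path, schema = birth_schema()) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- raw[unname(schema)]
  names(df) <- names(schema)
  as_birth_records(df)
}

#' Coerce and validate a data frame of birth records
#'
#' The in-memory counterpart of [read_birth_records()]: coerces types
#' (dates, integers, logicals) and enforces the record invariants.
#'
#' @param df Data frame with the canonical columns of [birth_schema()].
#' @return The validated cohort data frame.
#' @export
as_birth_records <- function(df) {
  need <- names(birth_schema())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  df$record_id <- as.character(df$record_id)
  if (!inherits(df$birth_date, "Date")) {
    df$birth_date <- as.Date(as.character(df$birth_date), format = "%Y-%m-%d")
  }
  for (f in c("gestational_age_days", "plurality", "apgar5", "imd_quintile")) {
    df[[f]] <- suppressWarnings(as.integer(df[[f]]))
  }
  for (f in c("antenatally_diagnosed_breech", "planned_cesarean_for_breech",
              "nnu_admission", "hie", "perinatal_death", "congenital_anomaly",
              "parous")) {
    df[[f]] <- .as_logical(df[[f]])
  }
  for (f in c("maternal_age_years", "bmi")) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }
  df$ethnicity <- as.character(df$ethnicity)
  probs <- .validate_rows(df)
  if (length(probs)) {
    stop("invalid birth records (", length(probs), " problem(s)):\n  ",
         paste(utils::head(probs, 20), collapse = "\n  "),
         if (length(probs) > 20) "\n  ..." else "", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write a cohort to CSV
#'
#' Inverse of [read_birth_records()]: writes the canonical columns with
#' ISO-8601 dates so that a written cohort reads back identically.
#'
#' @param records Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_birth_records <- function(records, path) {
  out <- records
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Epoch assignment rule
#'
#' Births strictly before `cut_date` belong to the "before" epoch; births
#' on or after it to the "after" epoch (half-open interval).
#'
#' @param cut_date `Date` (or string) on which the screening policy took
#'   effect.
#' @param label_before,label_after Epoch labels used in summaries.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(cut_date, label_before = "before", label_after = "after") {
  cut_date <- as.Date(cut_date)
  if (is.na(cut_date)) stop("cut_date is not a valid date")
  structure(list(cut_date = cut_date, label_before = label_before,
                 label_after = label_after), class = "epoch_spec")
}

#' @export
print.epoch_spec <- function(x, ...) {
  cat("Epoch rule: '", x$label_before, "' < ", format(x$cut_date),
      " <= '", x$label_after, "'\n", sep = "")
  invisible(x)
}

#' Assign each record to an epoch
#'
#' @param records Cohort data frame.
#' @param epoch An [epoch_spec()].
#' @return Factor with levels `(label_before, label_after)`.
#' @export
assign_epoch <- function(records, epoch) {
  stopifnot(inherits(epoch, "epoch_spec"))
  factor(ifelse(records$birth_date < epoch$cut_date,
                epoch$label_before, epoch$label_after),
         levels = c(epoch$label_before, epoch$label_after))
}

#' Apply the cohort exclusion criteria
#'
#' Removes multiple pregnancies (plurality > 1), preterm births
#' (gestational age < 259 days, i.e. below 37+0 weeks) and births with a
#' congenital anomaly. A record meeting several criteria is tallied under
#' the first matching reason, in that order.
#'
#' @param records Cohort data frame.
#' @return List with `kept` (the filtered data frame) and `excluded`
#'   (named integer tally by reason, summing to `nrow(records) - nrow(kept)`).
#' @export
apply_exclusions <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$plurality > 1] <- "multiple_pregnancy"
  reason[is.na(reason) & records$gestational_age_days < 259] <- "preterm"
  reason[is.na(reason) & records$congenital_anomaly] <- "congenital_anomaly"
  tally <- c(
    multiple_pregnancy = sum(reason == "multiple_pregnancy", na.rm = TRUE),
    preterm = sum(reason == "preterm", na.rm = TRUE),
    congenital_anomaly = sum(reason == "congenital_anomaly", na.rm = TRUE)
  )
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = tally)
}

#' Planned-cesarean-for-breech rule
#'
#' Pregnancies delivered by planned cesarean for breech presentation are
#' excluded from non-neonatal outcome denominators but retained for
#' neonatal outcomes (Apgar < 7, neonatal-unit admission, hypoxic ischemic
#' encephalopathy, perinatal death).
#'
#' @param records Cohort data frame.
#' @param outcome_name A registered outcome name (see [outcome_registry()]).
#' @return The (possibly filtered) cohort data frame.
#' @export
apply_planned_cs_rule <- function(records, outcome_name) {
  def <- outcome_def(outcome_name)
  if (def$neonatal) return(records)
  kept <- records[!records$planned_cesarean_for_breech, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Classify undiagnosed breech presentation
#'
#' A term breech birth counts as undiagnosed when breech presentation was
#' not identified antenatally and was first found (a) after the onset of
#' labour or rupture of membranes, or (b) immediately before commencing
#' induction of labour.
#'
#' @param records Cohort data frame of term breech births only.
#' @return Logical vector, one element per record.
#' @export
classify_undiagnosed_breech <- function(records) {
  if (any(records$presentation_at_birth != "breech")) {
    stop("classify_undiagnosed_breech() called on non-breech record(s)")
  }
  !records$antenatally_diagnosed_breech &
    records$onset %in% c("spontaneous_labour", "prelabour_ROM", "induction")
}

#' Two-epoch outcome summary (2x2 counts)
#'
#' @param outcome_name Registered outcome name, or a free label for
#'   hand-built summaries.
#' @param events Integer pair `(before, after)` event counts.
#' @param totals Integer pair `(before, after)` denominators.
#' @param epoch_labels Character pair of epoch labels.
#' @return Object of class `cohort_summary`.
#' @export
cohort_summary <- function(outcome_name, events, totals,
                           epoch_labels = c("before", "after")) {
  events <- as.integer(events); totals <- as.integer(totals)
  stopifnot(length(events) == 2, length(totals) == 2,
            length(epoch_labels) == 2)
  if (any(totals <= 0)) stop("totals must be positive")
  if (any(events < 0) || any(events > totals)) {
    stop("events must satisfy 0 <= events <= totals")
  }
  structure(list(outcome_name = outcome_name,
                 epoch_labels = as.character(epoch_labels),
                 events = events, totals = totals),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  pct <- proportions_pct(x)
  cat(sprintf("%s: %s %d/%d (%.1f%%) vs %s %d/%d (%.1f%%)\n",
              x$outcome_name, x$epoch_labels[1], x$events[1], x$totals[1],
              pct[1], x$epoch_labels[2], x$events[2], x$totals[2], pct[2]))
  invisible(x)
}

#' Epoch percentages of a summary
#'
#' @param summary A [cohort_summary()].
#' @return Numeric pair `100 * events / totals`.
#' @export
proportions_pct <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  100 * summary$events / summary$totals
}

#' Aggregate a cohort into a two-epoch outcome summary
#'
#' Counts outcome events and denominators per epoch. Records missing a
#' field required by the outcome (e.g. Apgar score for `apgar_lt7`) are
#' dropped from that outcome's denominator only; the number dropped is
#' attached as attribute `n_dropped_missing`.
#'
#' @param records Cohort data frame, already passed through
#'   [apply_exclusions()] and [apply_planned_cs_rule()] for this outcome.
#' @param epoch An [epoch_spec()].
#' @param outcome_name Registered outcome name.
#' @param denominator `"breech_births"` (default) restricts the denominator
#'   to births with breech presentation; `"all_births"` uses every record.
#' @return A [cohort_summary()].
#' @export
summarise_outcome <- function(records, epoch, outcome_name,
                              denominator = c("breech_births", "all_births")) {
  denominator <- match.arg(denominator)
  def <- outcome_def(outcome_name)
  if (denominator == "breech_births") {
    records <- records[records$presentation_at_birth == "breech", , drop = FALSE]
  }
  ok <- stats::complete.cases(records[def$requires])
  n_dropped <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  ep <- assign_epoch(records, epoch)
  totals <- as.integer(table(ep))
  if (any(totals == 0)) {
    empty <- c(epoch$label_before, epoch$label_after)[totals == 0]
    stop("epoch '", empty[1], "' contains no records for outcome '",
         outcome_name, "'")
  }
  ev <- def$event(records)
  events <- as.integer(tapply(ev, ep, sum))
  out <- cohort_summary(outcome_name, events, totals,
                        c(epoch$label_before, epoch$label_after))
  attr(out, "n_dropped_missing") <- n_dropped
  out
}

#' Serialise a summary as JSON
#'
#' @param summary A [cohort_summary()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
summary_to_json <- function(summary, path = NULL) {
  pct <- proportions_pct(summary)
  x <- list(outcome = summary$outcome_name,
            epochs = summary$epoch_labels,
            events = summary$events, totals = summary$totals,
            percent = pct)
  js <- jsonlite::toJSON(x, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
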