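# End-to-end orchestration: read -> exclusions -> per-outcome
# planned-cesarean rule -> summaries -> descriptives -> Bayesian fits
# (flat + optional informative) -> number needed to scan -> interrupted
# time series, with table-shaped TSV/JSON artifacts and a run log.

#' Full-analysis configuration
#'
#' @param input Path to a record-level CSV, or a cohort data frame.
#' @param cut_date Policy-change date (see [epoch_spec()]).
#' @param outcomes Data frame with columns `name` (registered outcome) and
#'   `denominator` (`"breech_births"` or `"all_births"`).
#' @param priors Named list mapping outcome names to [rr_prior()] objects
#'   for the informative-prior fits; outcomes absent from the list get the
#'   flat (weakly-informative) fit only.
#' @param mcmc An [mcmc_config()]; its seed drives every stochastic stage.
#' @param its_spline_df Spline df for the interrupted time series.
#' @param out_dir Output directory for report artifacts (created).
#' @param labels Epoch labels.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(input, cut_date,
                            outcomes = data.frame(
                              name = c("undiagnosed_breech", "apgar_lt7",
                                       "nnu_admission", "hie", "perinatal_death"),
                              denominator = "breech_births"),
                            priors = list(), mcmc = mcmc_config(),
                            its_spline_df = 4, out_dir = NULL,
                            labels = c("before", "after")) {
  reg <- names(outcome_registry())
  bad <- setdiff(outcomes$name, reg)
  if (length(bad)) {
    stop("unknown outcome(s) in config: ", paste(bad, collapse = ", "))
  }
  bad_p <- setdiff(names(priors), outcomes$name)
  if (length(bad_p)) {
    stop("priors supplied for unconfigured outcome(s): ",
         paste(bad_p, collapse = ", "))
  }
  structure(list(input = input, cut_date = as.Date(cut_date),
                 outcomes = outcomes, priors = priors, mcmc = mcmc,
                 its_spline_df = its_spline_df, out_dir = out_dir,
                 labels = labels),
            class = "analysis_config")
}

.fit_row <- function(outcome, summ, fit, label) {
  pct <- proportions_pct(summ)
  data.frame(outcome = outcome, prior = label,
             events_before = summ$events[1], total_before = summ$totals[1],
             pct_before = pct[1],
             events_after = summ$events[2], total_after = summ$totals[2],
             pct_after = pct[2],
             rr_median = if (is.null(fit)) NA_real_ else fit$rr_median,
             cri_low = if (is.null(fit)) NA_real_ else fit$cri_low,
             cri_high = if (is.null(fit)) NA_real_ else fit$cri_high,
             prob_reduction_pct = if (is.null(fit)) NA_real_
                                  else 100 * fit$prob_reduction,
             stringsAsFactors = FALSE)
}

#' Run the full screening-policy analysis
#'
#' Executes every pipeline stage on one cohort and writes the report
#' bundle: an outcome table shaped like the study's per-cohort tables
#' (counts, percentages, flat- and informative-prior risk ratios with
#' credible intervals and posterior probabilities), a descriptive
#' comparison table, number needed to scan, the interrupted time-series
#' result, and a run log recording the seed and any convergence warnings.
#' Outcomes with zero events in both epochs are reported as not estimable;
#' single zero cells receive the single-event correction before fitting.
#' Any stage failure aborts with the stage name, and partially written
#' outputs are removed.
#'
#' @param config An [analysis_config()].
#' @return List with `summaries`, `descriptives`, `outcome_table`, `fits`,
#'   `nns`, `its`, `excluded` and (if `out_dir` was set) `paths`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- config$out_dir
  written <- character(0)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    invisible(path)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  stage <- "read"
  result <- tryCatch({
    records <- if (is.data.frame(config$input)) as_birth_records(config$input)
               else read_birth_records(config$input)
    epoch <- epoch_spec(config$cut_date, config$labels[1], config$labels[2])

    stage <- "exclusions"
    ex <- apply_exclusions(records)
    kept <- ex$kept

    stage <- "descriptives"
    desc <- describe_epochs(kept, epoch)

    stage <- "summaries"
    log_lines <- c(sprintf("seed: %d", config$mcmc$seed),
                   sprintf("R version: %s", getRversion()),
                   sprintf("records: %d read, %d after exclusions",
                           nrow(records), nrow(kept)),
                   sprintf("excluded: %s",
                           paste(names(ex$excluded), ex$excluded,
                                 sep = "=", collapse = ", ")))
    summaries <- list(); fits <- list(); rows <- list()
    for (i in seq_len(nrow(config$outcomes))) {
      oc <- config$outcomes$name[i]
      denom <- config$outcomes$denominator[i]
      recs_o <- apply_planned_cs_rule(kept, oc)
      summ <- summarise_outcome(recs_o, epoch, oc, denom)
      summaries[[oc]] <- summ

      stage <- paste0("bayes:", oc)
      if (all(summ$events == 0L)) {
        log_lines <- c(log_lines, sprintf("%s: no events in either epoch; not estimable", oc))
        rows[[length(rows) + 1]] <- .fit_row(oc, summ, NULL, "flat")
        next
      }
      fsumm <- zero_event_correction(summ)
      if (isTRUE(attr(fsumm, "corrected"))) {
        log_lines <- c(log_lines, sprintf("%s: single-event correction applied", oc))
      }
      flat <- withCallingHandlers(
        sensitivity_flat(fsumm, config$mcmc),
        warning = function(w) {
          log_lines <<- c(log_lines, sprintf("%s (flat): %s", oc, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      fits[[oc]] <- list(flat = flat)
      rows[[length(rows) + 1]] <- .fit_row(oc, summ, flat, "flat")
      if (oc %in% names(config$priors)) {
        inf <- withCallingHandlers(
          fit_logbinomial(fsumm, config$priors[[oc]], config$mcmc),
          warning = function(w) {
            log_lines <<- c(log_lines, sprintf("%s (informative): %s", oc, conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        fits[[oc]]$informative <- inf
        rows[[length(rows) + 1]] <- .fit_row(oc, summ, inf, "informative")
      }
    }
    outcome_table <- do.call(rbind, rows)

    stage <- "nns"
    nns <- if ("undiagnosed_breech" %in% config$outcomes$name) {
      recs_u <- apply_planned_cs_rule(kept, "undiagnosed_breech")
      summ_all <- summarise_outcome(recs_u, epoch, "undiagnosed_breech",
                                    "all_births")
      tryCatch(number_needed_to_scan(summ_all), error = function(e) {
        log_lines <<- c(log_lines, paste("nns:", conditionMessage(e)))
        NULL
      })
    } else NULL

    stage <- "its"
    breech <- kept[kept$presentation_at_birth == "breech", , drop = FALSE]
    its <- fit_its(aggregate_monthly(breech, epoch),
                   spline_df = config$its_spline_df)

    stage <- "write"
    emit("outcome_table.tsv", function(p) {
      utils::write.table(outcome_table, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
    })
    emit("descriptives.tsv", function(p) {
      utils::write.table(desc, p, sep = "\t", row.names = FALSE, quote = FALSE)
    })
    emit("report.json", function(p) {
      payload <- list(
        outcome_table = outcome_table,
        nns = if (is.null(nns)) NULL else nns[c("nns", "ci", "rd", "rd_ci")],
        its = if (is.null(its)) NULL else
          its[c("epoch_effect", "f_statistic", "p_value", "spline_df")],
        excluded = as.list(ex$excluded),
        seed = config$mcmc$seed)
      writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, na = "null"), p)
    })
    emit("run.log", function(p) writeLines(log_lines, p))

    list(summaries = summaries, descriptives = desc,
         outcome_table = outcome_table, fits = fits, nns = nns, its = its,
         excluded = ex$excluded, log = log_lines,
         paths = if (is.null(out_dir)) NULL else written)
  }, error = function(e) {
    unlink(written)
    stop("analysis failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}
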