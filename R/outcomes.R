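#' Registered perinatal outcomes
#'
#' Each outcome the pipeline can tabulate is registered with an event
#' predicate (a function of the cohort data frame returning a logical
#' vector), the fields it requires to be non-missing, and whether it is a
#' neonatal outcome. Neonatal outcomes (low Apgar, neonatal-unit admission,
#' hypoxic ischemic encephalopathy, extended perinatal mortality) keep
#' pregnancies delivered by planned cesarean for breech in their
#' denominator; all other outcomes drop them (see
#' [apply_planned_cs_rule()]).
#'
#' @return A named list of outcome definitions, each with elements
#'   `name`, `neonatal`, `requires` and `event`.
#' @seealso [summarise_outcome()], [apply_planned_cs_rule()]
#' @export
#' @examples
#' names(outcome_registry())
#' outcome_registry()$apgar_lt7$neonatal
outcome_registry <- function() {
  list(
    undiagnosed_breech = list(
      name = "undiagnosed_breech", neonatal = FALSE,
      requires = c("presentation_at_birth", "antenatally_diagnosed_breech", "onset"),
      event = function(df) {
        df$presentation_at_birth == "breech" &
          !df$antenatally_diagnosed_breech &
          df$onset %in% c("spontaneous_labour", "prelabour_ROM", "induction")
      }
    ),
    apgar_lt7 = list(
      name = "apgar_lt7", neonatal = TRUE, requires = "apgar5",
      event = function(df) df$apgar5 < 7
    ),
    nnu_admission = list(
      name = "nnu_admission", neonatal = TRUE, requires = "nnu_admission",
      event = function(df) df$nnu_admission
    ),
    hie = list(
      name = "hie", neonatal = TRUE, requires = "hie",
      event = function(df) df$hie
    ),
    perinatal_death = list(
      name = "perinatal_death", neonatal = TRUE, requires = "perinatal_death",
      event = function(df) df$perinatal_death
    ),
    elective_cesarean = list(
      name = "elective_cesarean", neonatal = FALSE, requires = "mode_of_birth",
      event = function(df) df$mode_of_birth == "elective_cesarean"
    ),
    emergency_cesarean = list(
      name = "emergency_cesarean", neonatal = FALSE, requires = "mode_of_birth",
      event = function(df) df$mode_of_birth == "emergency_cesarean"
    ),
    breech_presentation = list(
      name = "breech_presentation", neonatal = FALSE,
      requires = "presentation_at_birth",
      event = function(df) df$presentation_at_birth == "breech"
    ),
    vaginal_breech = list(
      name = "vaginal_breech", neonatal = FALSE, requires = "mode_of_birth",
      event = function(df) {
        df$mode_of_birth %in% c("vaginal_breech_spontaneous",
                                "vaginal_breech_extraction",
                                "vaginal_breech_forceps")
      }
    )
  )
}

outcome_def <- function(outcome_name) {
  reg <- outcome_registry()
  if (!outcome_name %in% names(reg)) {
    stop("unknown outcome '", outcome_name, "'; registered outcomes: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[outcome_name]]
}
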