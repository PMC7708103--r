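# Hierarchical cause-of-death assignment for neonatal deaths, following the
# Global Network algorithm family: congenital anomaly first, then infection,
# then gestational-age (or, when GA is missing, birth-weight) banded rules
# separating asphyxia, prematurity and unknown.
#
# Boundary conventions (all config-visible via cod_thresholds()):
#   term                  GA >= 37.0 completed weeks
#   moderate preterm band GA in [34, 37) weeks, or weight in [2000, 2500) g
#                         when GA is missing
#   early preterm rule    GA < 34 weeks and/or weight < 2000 g (strict)
# GA governs band membership whenever present; weight thresholds act only as
# a fallback for missing GA.

#' Gestational-age and birth-weight thresholds of the cause-of-death rules
#'
#' @return Named list of the classification boundaries in completed weeks
#'   and grams.
#' @export
cod_thresholds <- function() {
  list(term_ga = 37, moderate_ga_low = 34, weight_low = 2000,
       weight_high = 2500)
}

#' The five assignable causes of neonatal death
#' @return Character vector of the cause labels, in reporting order.
#' @export
cod_causes <- function() registry_enums$cause_of_death

.flag <- function(x) !is.na(x) & x

# Vectorized rule engine. `df` must carry the CODInput columns; returns a
# data frame with `cause` and `rule` (provenance code) per row.
.assign_cause_vec <- function(df) {
  th <- cod_thresholds()
  n <- nrow(df)
  ga <- df$ga_delivery_weeks
  wt <- df$birth_weight_g

  anomaly <- .flag(df$major_congenital_anomaly)
  infection <- .flag(df$tetanus) | .flag(df$omphalitis) | .flag(df$sepsis) |
    .flag(df$pneumonia) | .flag(df$infection_suspected)
  breathing <- .flag(df$breathing_difficulty_at_birth) |
    .flag(df$respiratory_distress)
  mat_comp <- .flag(df$maternal_pregnancy_complication)

  unclassifiable <- is.na(ga) & is.na(wt)
  # band membership: GA governs when present; weight is the fallback
  term <- ifelse(!is.na(ga), ga >= th$term_ga,
                 !is.na(wt) & wt >= th$weight_high)
  moderate <- ifelse(!is.na(ga),
                     ga >= th$moderate_ga_low & ga < th$term_ga,
                     !is.na(wt) & wt >= th$weight_low & wt < th$weight_high)
  early <- (!is.na(ga) & ga < th$moderate_ga_low) |
    (is.na(ga) & !is.na(wt) & wt < th$weight_low)

  cause <- rep(NA_character_, n)
  rule <- rep(NA_character_, n)

  set <- function(idx, cz, rl) {
    idx <- idx & is.na(cause)
    cause[idx] <<- cz
    rule[idx] <<- rl
  }

  set(anomaly, "congenital_anomaly", "anomaly")
  set(infection, "infection", "infection")
  set(unclassifiable, "unknown", "missing_ga_and_weight")
  set(term & breathing, "asphyxia", "term_asphyxia")
  set(term, "unknown", "term_no_signs")
  set(moderate & (breathing | mat_comp), "asphyxia", "moderate_asphyxia")
  # early preterm / very low weight rule ("<34 weeks and/or <2000 g")
  early_or_lowwt <- early | (!is.na(wt) & wt < th$weight_low)
  set(early_or_lowwt, "prematurity", "early_prematurity")
  # residual: moderate preterm band with no implicating sign. Not covered by
  # the quoted rule set; assigned prematurity as a preterm death with nothing
  # else implicated, and flagged with its own provenance code for audit.
  set(moderate, "prematurity", "moderate_preterm_residual")
  set(rep(TRUE, n), "unknown", "unassigned")

  if (any(rule == "missing_ga_and_weight")) {
    warning(sprintf(
      "%d record(s) with neither gestational age nor birth weight assigned 'unknown'",
      sum(rule == "missing_ga_and_weight")), call. = FALSE)
  }
  data.frame(cause = factor(cause, levels = cod_causes()), rule = rule,
             stringsAsFactors = FALSE)
}

#' Assign a cause of death to one neonatal death
#'
#' Deterministic hierarchy: (1) a major congenital anomaly dominates
#' everything; (2) else any infection sign or suspicion (tetanus, omphalitis,
#' sepsis, pneumonia, or suspected) gives infection; (3) else a term infant
#' (GA >= 37 weeks) with breathing difficulty at birth or respiratory
#' distress is asphyxia, a term infant without either is unknown; (4) else a
#' moderately preterm infant (GA 34 to <37 weeks, or 2000 to <2500 g when GA
#' is missing) with breathing difficulty and/or any maternal pregnancy
#' complication is asphyxia; (5) else GA < 34 weeks and/or weight < 2000 g is
#' complications of prematurity; (6) a remaining moderately preterm death
#' with no implicating sign is assigned prematurity with an audit code.
#' A record with neither GA nor weight is returned as unknown with a warning.
#'
#' @param input A named list or one-row data frame with the questionnaire
#'   fields: logical flags `major_congenital_anomaly`, `tetanus`,
#'   `omphalitis`, `sepsis`, `pneumonia`, `infection_suspected`,
#'   `breathing_difficulty_at_birth`, `respiratory_distress`,
#'   `maternal_pregnancy_complication`; numeric `ga_delivery_weeks`
#'   (completed weeks) and `birth_weight_g` (grams), either possibly missing.
#' @return A list with `cause` (one of [cod_causes()]) and `rule`, the
#'   provenance code of the rule that fired.
#' @examples
#' assign_cause(list(major_congenital_anomaly = TRUE, sepsis = TRUE,
#'                   ga_delivery_weeks = 28))
#' assign_cause(list(ga_delivery_weeks = 30, birth_weight_g = 1200))
#' @export
assign_cause <- function(input) {
  fields <- c("major_congenital_anomaly", "tetanus", "omphalitis", "sepsis",
              "pneumonia", "infection_suspected",
              "breathing_difficulty_at_birth", "respiratory_distress",
              "maternal_pregnancy_complication")
  df <- data.frame(row.names = 1)
  for (f in fields) df[[f]] <- isTRUE(input[[f]])
  for (f in c("ga_delivery_weeks", "birth_weight_g")) {
    v <- input[[f]]
    df[[f]] <- if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else
      as.numeric(v)
  }
  res <- .assign_cause_vec(df)
  list(cause = as.character(res$cause[1]), rule = res$rule[1])
}

#' Classify a set of neonatal deaths and tally causes
#'
#' Applies [assign_cause()] to every record; no record is ever dropped, so
#' the tally always sums to the number of input deaths.
#'
#' @param death_records Data frame of questionnaire records (the `cod` table,
#'   or the output of [cod_analysis_set()] joined to it).
#' @return A list with `assignments` (the input plus `cause` and `rule`
#'   columns) and `tally` (named integer vector over [cod_causes()]).
#' @export
classify_deaths <- function(death_records) {
  res <- .assign_cause_vec(death_records)
  out <- death_records
  out$cause <- res$cause
  out$rule <- res$rule
  tally <- table(res$cause)
  list(assignments = out, tally = stats::setNames(as.integer(tally),
                                                  names(tally)))
}
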