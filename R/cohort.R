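# Analysis-cohort construction: the exclusion cascade applied to a perinatal
# registry before any mortality analysis. Exclusions are applied in a fixed
# order and every drop is counted, so the ledger reconciles exactly with the
# input totals.

#' Build the live-birth analysis cohort
#'
#' Applies the standard registry exclusion cascade, in order: mothers not
#' resident in a study cluster, mothers who died before delivery, then
#' pregnancy losses (miscarriage, medically terminated pregnancy, stillbirth).
#' Every remaining live birth is one analysis row; infants of multiple
#' gestations each count once, sharing their mother's covariates. Missing
#' covariates are retained and handled complete-case per analysis downstream.
#'
#' @param maternal Decoded maternal table (one row per enrolled pregnancy).
#' @param infant Decoded infant table (one row per birth outcome).
#' @return An object of class `analysis_cohort`: a list with `data` (live
#'   births joined to maternal covariates), `ledger` (named exclusion counts),
#'   and summary counts (`screened`, `live_births`, `neonatal_deaths`).
#' @examples
#' reg <- generate_registry(simulation_config(n_clusters = 4, years = 2016,
#'                                            seed = 1))
#' cohort <- build_cohort(reg$maternal, reg$infant)
#' cohort$ledger
#' @export
build_cohort <- function(maternal, infant) {
  if (anyDuplicated(maternal$mother_id)) {
    dup <- maternal$mother_id[duplicated(maternal$mother_id)][1]
    stop(sprintf("duplicate mother_id '%s' in maternal table", dup),
         call. = FALSE)
  }
  if (anyDuplicated(infant$infant_id)) {
    dup <- infant$infant_id[duplicated(infant$infant_id)][1]
    stop(sprintf("duplicate infant_id '%s' in infant table", dup),
         call. = FALSE)
  }
  unknown <- setdiff(infant$mother_id, maternal$mother_id)
  if (length(unknown)) {
    stop(sprintf("infant table references unknown mother_id '%s'",
                 unknown[1]), call. = FALSE)
  }

  screened <- nrow(maternal)
  non_resident <- !is.na(maternal$resident_in_cluster) &
    !maternal$resident_in_cluster
  m1 <- maternal[!non_resident, , drop = FALSE]
  died_pre <- !is.na(m1$died_before_delivery) & m1$died_before_delivery
  m2 <- m1[!died_pre, , drop = FALSE]

  inf <- infant[infant$mother_id %in% m2$mother_id, , drop = FALSE]
  inf_excluded_maternal <- nrow(infant) - nrow(inf)
  outcome <- as.character(inf$birth_outcome)
  ledger <- c(
    non_resident = sum(non_resident),
    maternal_death_before_delivery = sum(died_pre),
    infants_of_excluded_mothers = inf_excluded_maternal,
    miscarriage = sum(outcome == "miscarriage", na.rm = TRUE),
    medical_termination = sum(outcome == "medical_termination", na.rm = TRUE),
    stillbirth = sum(outcome == "stillbirth", na.rm = TRUE),
    missing_birth_outcome = sum(is.na(outcome))
  )
  live <- inf[!is.na(outcome) & outcome == "live_birth", , drop = FALSE]

  # stable order: deterministic regardless of input permutation
  live <- live[order(live$infant_id), , drop = FALSE]
  m2 <- m2[order(m2$mother_id), , drop = FALSE]
  joined <- merge(live, m2, by = "mother_id", sort = TRUE)
  joined <- joined[order(joined$infant_id), , drop = FALSE]
  rownames(joined) <- NULL
  joined$death_28d <- !joined$alive_at_28d
  joined <- .derive_analysis_columns(joined)

  structure(list(
    data = joined,
    ledger = ledger,
    screened = screened,
    mothers_retained = length(unique(joined$mother_id)),
    live_births = nrow(joined),
    neonatal_deaths = sum(joined$death_28d, na.rm = TRUE),
    input_infants = nrow(infant)
  ), class = "analysis_cohort")
}

#' @export
print.analysis_cohort <- function(x, ...) {
  cat("Analysis cohort:", x$live_births, "live births from",
      x$mothers_retained, "mothers;", x$neonatal_deaths,
      "neonatal deaths (<28 d)\n")
  cat("Exclusions:\n")
  for (k in names(x$ledger)) cat(sprintf("  %-32s %d\n", k, x$ledger[[k]]))
  invisible(x)
}

# Derived analysis variables: birth-weight bands, preterm indicator, the
# negated GA used for per-week-decrease risk ratios, and reference levels
# matching registry reporting convention (largest/most favourable group as
# reference).
.derive_analysis_columns <- function(d) {
  d$bw_category <- cut(d$birth_weight_g,
                       breaks = c(-Inf, 1000, 1500, 2500, Inf),
                       right = FALSE,
                       labels = c("lt1000", "1000-1499", "1500-2499",
                                  "2500plus"))
  d$bw_category <- stats::relevel(d$bw_category, ref = "2500plus")
  d$preterm <- d$ga_delivery_weeks < 37
  d$ga_weeks_decrease <- -d$ga_delivery_weeks
  refs <- c(parity_category = "1-2", anc_visits_category = "4plus",
            education = "university_plus", age_category = "20-25",
            bmi_category = "normal", ga_at_enrollment_category = "lt8")
  for (v in names(refs)) {
    if (v %in% names(d) && is.factor(d[[v]])) {
      d[[v]] <- stats::relevel(d[[v]], ref = refs[[v]])
    }
  }
  d
}

#' Deaths eligible for cause-of-death analysis
#'
#' Restricts the cohort to neonatal deaths (died at <= 28 days) with a
#' completed cause-of-death questionnaire; deaths missing the form are
#' counted but dropped.
#'
#' @param cohort An `analysis_cohort`.
#' @return A list with `deaths` (the retained rows), `retained` and
#'   `dropped_missing_form` counts.
#' @export
cod_analysis_set <- function(cohort) {
  stopifnot(inherits(cohort, "analysis_cohort"))
  d <- cohort$data[cohort$data$death_28d %in% TRUE, , drop = FALSE]
  has_form <- d$cod_form_available %in% TRUE
  list(
    deaths = d[has_form, , drop = FALSE],
    retained = sum(has_form),
    dropped_missing_form = sum(!has_form)
  )
}
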