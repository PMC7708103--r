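# End-to-end pipeline: simulate (or load) -> cohort -> cause classification
# -> descriptive tables -> relative risks -> predictive model. Every stage
# writes its artifact before the next starts, so a failing stage leaves the
# preceding outputs on disk; the run is a pure function of (inputs, config,
# seed).

#' Load a simulation configuration from YAML
#'
#' Reads a YAML file with any subset of [simulation_config()] arguments;
#' unspecified fields keep their defaults. A `seed` argument overrides the
#' file.
#'
#' @param path YAML file path.
#' @param seed Optional seed override.
#' @return A `simulation_config`.
#' @export
load_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in intersect(names(raw), c("exclusion_fractions", "cause_mixture"))) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$covariate_marginals)) {
    raw$covariate_marginals <- lapply(raw$covariate_marginals, unlist)
  }
  if (!is.null(raw$enc_treatment_rates)) {
    raw$enc_treatment_rates <- lapply(raw$enc_treatment_rates, unlist)
  }
  do.call(simulation_config, raw)
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[pipeline] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Simulates a registry (or loads one from CSVs), builds the analysis
#' cohort, classifies causes of death, computes the descriptive tables,
#' estimates crude and cluster-adjusted relative risks, runs QIC forward
#' selection, and writes all intermediate CSVs plus one JSON summary.
#'
#' @param config A `simulation_config` (ignored when `input_dir` is given).
#' @param out_dir Output directory.
#' @param input_dir Optional directory holding `maternal.csv`, `infant.csv`,
#'   `cod.csv` to analyse instead of simulating.
#' @param risk_variables Exposures for the one-variable-at-a-time risk
#'   table.
#' @param candidates Candidate variables for forward selection.
#' @param verbose Log stage progress and record counts.
#' @return The summary list (also written to `summary.json`), invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir,
                         input_dir = NULL,
                         risk_variables = c("preterm", "multiple_gestation",
                                            "parity_category",
                                            "anc_visits_category",
                                            "education", "bw_category"),
                         candidates = predictive_candidates(),
                         verbose = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(input_dir)) {
      stopifnot(inherits(config, "simulation_config"))
      reg <- generate_registry(config)
      write_registry(reg, out_dir)
      .stage_log(verbose, "simulated %d pregnancies, %d infants",
                 reg$truth$n_pregnancies, reg$truth$n_infants)
      tables <- reg[c("maternal", "infant", "cod")]
    } else {
      tables <- read_tables(file.path(input_dir, "maternal.csv"),
                            file.path(input_dir, "infant.csv"),
                            file.path(input_dir, "cod.csv"))
    }

    stage <- "cohort"
    cohort <- build_cohort(tables$maternal, tables$infant)
    write_registry_csv(cohort$data, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(as.list(cohort$ledger),
                         file.path(out_dir, "exclusion_ledger.json"),
                         auto_unbox = TRUE)
    .stage_log(verbose, "cohort: %d live births, %d deaths",
               cohort$live_births, cohort$neonatal_deaths)

    stage <- "classify-cod"
    cod_set <- cod_analysis_set(cohort)
    cod_records <- tables$cod[tables$cod$infant_id %in%
                                cod_set$deaths$infant_id, , drop = FALSE]
    classified <- classify_deaths(cod_records)
    write_registry_csv(classified$assignments,
                       file.path(out_dir, "cod_assignments.csv"))
    .stage_log(verbose, "classified %d deaths (%d missing forms dropped)",
               nrow(cod_records), cod_set$dropped_missing_form)

    stage <- "describe"
    yr <- cohort$data$delivery_year[match(cod_records$infant_id,
                                          cohort$data$infant_id)]
    rates <- neonatal_mortality_rate(cohort, stratify_by_year = TRUE)
    causes <- cause_distribution(classified$assignments$cause, year = yr)
    utils::write.csv(rates, file.path(out_dir, "mortality_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(causes, file.path(out_dir, "cause_distribution.csv"),
                     row.names = FALSE)

    stage <- "risks"
    risks <- risk_table(cohort, risk_variables)
    utils::write.csv(risks, file.path(out_dir, "risk_estimates.csv"),
                     row.names = FALSE)

    stage <- "predict"
    sel <- forward_select(cohort, candidates)
    utils::write.csv(sel$steps, file.path(out_dir, "selection_path.csv"),
                     row.names = FALSE)
    utils::write.csv(sel$final$summary,
                     file.path(out_dir, "final_model.csv"),
                     row.names = FALSE)

    stage <- "summary"
    summary <- list(
      schema_version = registry_schema()$version,
      exclusion_ledger = as.list(cohort$ledger),
      live_births = cohort$live_births,
      neonatal_deaths = cohort$neonatal_deaths,
      mortality_rates = rates,
      cause_distribution = causes,
      cod_deaths_classified = nrow(cod_records),
      cod_forms_missing = cod_set$dropped_missing_form,
      risk_estimates = risks,
      selection = list(selected = sel$selected, steps = sel$steps,
                       marginal_r2 = sel$final$marginal_r2),
      final_model = sel$final$summary
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows")
    summary
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
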