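# Fixture builders and independent oracles shared across the suite.

# A minimal maternal row; override any field via ...
make_mother <- function(mother_id, cluster_id = "C01", year = 2015, ...) {
  row <- data.frame(
    mother_id = mother_id, cluster_id = cluster_id, delivery_year = year,
    resident_in_cluster = TRUE, died_before_delivery = FALSE,
    age_category = factor("20-25", levels = registry_enums$age_category),
    education = factor("primary_secondary", levels = registry_enums$education),
    bmi_category = factor("normal", levels = registry_enums$bmi_category),
    parity_category = factor("1-2", levels = registry_enums$parity_category),
    anc_visits_category = factor("4plus",
                                 levels = registry_enums$anc_visits_category),
    ga_at_enrollment_category = factor("lt8",
      levels = registry_enums$ga_at_enrollment_category),
    delivery_attendant = factor("obstetrician",
                                levels = registry_enums$delivery_attendant),
    delivery_location = factor("hospital",
                               levels = registry_enums$delivery_location),
    pregnancy_complication = FALSE, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

make_infant <- function(infant_id, mother_id, outcome = "live_birth",
                        alive = TRUE, ...) {
  row <- data.frame(
    infant_id = infant_id, mother_id = mother_id,
    birth_outcome = factor(outcome, levels = registry_enums$birth_outcome),
    birth_weight_g = 3000, ga_delivery_weeks = 39,
    multiple_gestation = FALSE,
    alive_at_28d = if (outcome == "live_birth") alive else NA,
    age_at_death_days = if (outcome == "live_birth" && !alive) 3 else
      NA_real_,
    skin_to_skin = TRUE, bathed_within_6h = FALSE,
    breastfed_within_1h = TRUE, bag_mask = FALSE, antibiotics = FALSE,
    oxygen = FALSE, cpap = FALSE, mech_vent = FALSE,
    cod_form_available = if (outcome == "live_birth" && !alive) TRUE else NA,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

bind_rows_base <- function(lst) do.call(rbind, lst)

# Independently written nested-if oracle for the cause-of-death hierarchy.
# Deliberately structured differently from the package implementation
# (scalar early returns; explicit weight fallback branch).
cod_oracle <- function(anomaly = FALSE, tetanus = FALSE, omphalitis = FALSE,
                       sepsis = FALSE, pneumonia = FALSE, suspected = FALSE,
                       ga = NA, wt = NA, breath = FALSE, distress = FALSE,
                       matcomp = FALSE) {
  if (anomaly) return("congenital_anomaly")
  if (tetanus || omphalitis || sepsis || pneumonia || suspected) {
    return("infection")
  }
  if (is.na(ga) && is.na(wt)) return("unknown")
  if (!is.na(ga)) {
    if (ga >= 37) {
      if (breath || distress) return("asphyxia")
      return("unknown")
    }
    if (ga >= 34) {
      if (breath || distress || matcomp) return("asphyxia")
      return("prematurity")
    }
    return("prematurity")
  }
  if (wt >= 2500) {
    if (breath || distress) return("asphyxia")
    return("unknown")
  }
  if (wt >= 2000) {
    if (breath || distress || matcomp) return("asphyxia")
    return("prematurity")
  }
  "prematurity"
}

# small desk-scale configs used by simulation-based tests
desk_config <- function(seed, n_clusters = 20, years = 2016,
                        deliveries = c(240, 260), ...) {
  simulation_config(n_clusters = n_clusters, years = years,
                    deliveries_per_cluster_year = deliveries, seed = seed,
                    ...)
}

# single-effect risk model: education no_formal carries log-RR `b`,
# everything else null
single_effect_risk <- function(b, baseline = 0.02, cluster_sd = 0.2) {
  list(baseline_risk = baseline,
       log_rr = list(education = c(no_formal = b, primary_secondary = 0)),
       cluster_sd = cluster_sd, year_log_rr = 0)
}

# crude 2x2 for a binary-ish exposure from a cohort data frame
cohort_two_by_two <- function(d, expose) {
  idx <- !is.na(expose)
  e <- expose[idx]; y <- d$death_28d[idx]
  two_by_two(sum(y & e), sum(e), sum(y & !e), sum(!e))
}
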