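# Seeded generator of synthetic clustered perinatal registry data with the
# statistical structure the analysis pipeline assumes: geographic clusters of
# 300-500 deliveries per year, maternal covariates drawn from registry-style
# marginals, gestational age as a term/preterm mixture with birth weight
# conditional on GA, a log-link risk model with a cluster random effect for
# 28-day death, latent causes of death emitting questionnaire signs at a
# configurable fidelity, and an exclusion cascade (non-resident mothers,
# pre-delivery maternal deaths, miscarriages, terminations, stillbirths).
#
# Random number draws are split into per-phase streams (structure,
# covariates, outcomes, deaths, signs) so extending one phase does not
# perturb draws in another across package versions.

.norm_counts <- function(x) x / sum(x)

.default_marginals <- function() list(
  # level frequencies of infants alive at day 28 in a large rural Indian
  # registry population; used as the generating covariate marginals
  age_category        = .norm_counts(c(`lt20` = 3842, `20-25` = 20299,
                                       `26-30` = 5309, `gt30` = 735)),
  education           = .norm_counts(c(no_formal = 3555,
                                       primary_secondary = 23434,
                                       university_plus = 3194)),
  bmi_category        = .norm_counts(c(underweight = 10406, normal = 17633,
                                       overweight = 2126)),
  parity_category     = .norm_counts(c(`0` = 11585, `1-2` = 16561,
                                       `3plus` = 2037)),
  anc_visits_category = .norm_counts(c(`0-1` = 127, `2` = 914, `3` = 6152,
                                       `4plus` = 22990)),
  ga_at_enrollment_category = .norm_counts(c(`lt8` = 10892, `8-11.6` = 11006,
                                             `12-20` = 6422, `gt20` = 1771)),
  delivery_attendant  = .norm_counts(c(obstetrician = 15192,
                                       non_ob_physician = 3212,
                                       nurse_midwife = 10996, tba = 102,
                                       family = 589, self = 81, other = 9)),
  delivery_location   = .norm_counts(c(hospital = 21607,
                                       clinic_health_center = 7485,
                                       home = 753, other = 337))
)

.default_enc_rates <- function() list(
  # P(flag | died), P(flag | alive)
  skin_to_skin        = c(died = 0.088, alive = 0.241),
  bathed_within_6h    = c(died = 0.004, alive = 0.004),
  breastfed_within_1h = c(died = 0.175, alive = 0.700),
  bag_mask            = c(died = 0.503, alive = 0.034),
  antibiotics         = c(died = 0.473, alive = 0.061),
  oxygen              = c(died = 0.556, alive = 0.054),
  cpap                = c(died = 0.195, alive = 0.014),
  mech_vent           = c(died = 0.160, alive = 0.005)
)

#' Build a simulation configuration
#'
#' All defaults describe the registry population the generator emulates: the
#' exclusion-cascade fractions, covariate marginals, gestational-age mixture
#' (term component mean 38.8, sd 2.3 weeks), birth weight conditional on GA,
#' the log-link death-risk model with a cluster random effect, the target
#' cause-of-death mixture among deaths, and essential-newborn-care /
#' treatment rates conditional on vital status. The configuration is
#' validated eagerly: a risk model that implies a death probability above 1
#' for any covariate pattern (including the cluster effect at its truncation
#' bound) is a hard error naming the offending pattern.
#'
#' @param n_clusters Number of geographic study clusters.
#' @param deliveries_per_cluster_year Integer range (length 2) of deliveries
#'   per cluster-year.
#' @param years Calendar years covered.
#' @param exclusion_fractions Named vector: `non_resident` (of screened
#'   women), `maternal_death` (of resident women, before delivery),
#'   `miscarriage`, `termination`, `stillbirth` (of remaining pregnancies).
#' @param covariate_marginals Named list of level-probability vectors.
#' @param ga_distribution List: `preterm_prob`, `preterm_prob_multiple`,
#'   `term_mean`, `term_sd`, `preterm_mean`, `preterm_sd` (weeks). Term
#'   draws are truncated to `[37, 44]`, preterm to `[22, 37)`.
#' @param weight_given_ga List: `mean_at_term`, `slope_per_week`, `sd`
#'   (grams); the conditional mean is linear in GA around 38.8 weeks.
#' @param risk_model List: `baseline_risk` (28-day death probability of the
#'   reference covariate pattern), `log_rr` (named list of named log
#'   relative-risk vectors keyed by analysis variable level), `cluster_sd`
#'   (SD of the cluster random effect on the log scale, truncated at
#'   +/- 2.5 SD), `year_log_rr` (log-RR per calendar year after the first;
#'   0 disables the secular trend).
#' @param cause_mixture Target cause probabilities conditional on death.
#' @param sign_fidelity Probability each latent cause emits its defining
#'   questionnaire sign.
#' @param multiple_prob Probability a pregnancy is a twin gestation.
#' @param pregnancy_complication_prob Maternal complication prevalence.
#' @param cod_form_missing_prob Probability a death is missing its
#'   questionnaire.
#' @param enc_treatment_rates Named list of `c(died=, alive=)` probabilities.
#' @param seed Mandatory integer seed.
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(
    n_clusters = 20,
    deliveries_per_cluster_year = c(300, 500),
    years = 2014:2018,
    exclusion_fractions = c(non_resident = 8578 / 47614,
                            maternal_death = 11 / 39036,
                            miscarriage = 4929 / 39025,
                            termination = 2542 / 39025,
                            stillbirth = 884 / 39025),
    covariate_marginals = .default_marginals(),
    ga_distribution = list(preterm_prob = 3235 / 30944,
                           preterm_prob_multiple = 0.55,
                           term_mean = 38.8, term_sd = 2.3,
                           preterm_mean = 33.5, preterm_sd = 3.0),
    weight_given_ga = list(mean_at_term = 2900, slope_per_week = 165,
                           sd = 420),
    risk_model = list(
      baseline_risk = 0.009,
      log_rr = list(
        bw_category = c(`lt1000` = 3.0, `1000-1499` = 2.8,
                        `1500-2499` = 1.15),
        anc_visits_category = c(`0-1` = 0.45, `2` = 0.32, `3` = 0.18),
        parity_category = c(`0` = 0.25, `3plus` = 0.40),
        education = c(no_formal = 0.35, primary_secondary = 0.18)),
      cluster_sd = 0.2,
      year_log_rr = 0),
    cause_mixture = c(congenital_anomaly = 0.184, infection = 0.237,
                      prematurity = 0.279, asphyxia = 0.251,
                      unknown = 0.049),
    sign_fidelity = 0.9,
    multiple_prob = 287 / 30657,
    pregnancy_complication_prob = 0.10,
    cod_form_missing_prob = 8 / 758,
    enc_treatment_rates = .default_enc_rates(),
    seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(seed == floor(seed), seed >= 0, seed < 2^31 - 10)
  cfg <- list(
    n_clusters = n_clusters,
    deliveries_per_cluster_year = deliveries_per_cluster_year,
    years = years, exclusion_fractions = exclusion_fractions,
    covariate_marginals = covariate_marginals,
    ga_distribution = ga_distribution, weight_given_ga = weight_given_ga,
    risk_model = risk_model, cause_mixture = cause_mixture,
    sign_fidelity = sign_fidelity, multiple_prob = multiple_prob,
    pregnancy_complication_prob = pregnancy_complication_prob,
    cod_form_missing_prob = cod_form_missing_prob,
    enc_treatment_rates = enc_treatment_rates, seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' Validate a simulation configuration
#'
#' Checks probability ranges, mixture normalization and — critically — that
#' the log-link risk model cannot imply a death probability above 1 for any
#' covariate pattern once the cluster random effect sits at its truncation
#' bound (+2.5 SD).
#'
#' @param cfg A configuration list (as built by [simulation_config()]).
#' @return `cfg`, invisibly, or an error.
#' @export
validate_simulation_config <- function(cfg) {
  probs <- c(cfg$exclusion_fractions, cfg$sign_fidelity, cfg$multiple_prob,
             cfg$pregnancy_complication_prob, cfg$cod_form_missing_prob,
             cfg$risk_model$baseline_risk,
             unlist(cfg$covariate_marginals), cfg$cause_mixture,
             unlist(cfg$enc_treatment_rates))
  if (any(probs < 0 | probs > 1)) {
    stop("configuration probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (nm in names(cfg$covariate_marginals)) {
    if (abs(sum(cfg$covariate_marginals[[nm]]) - 1) > 1e-8) {
      stop(sprintf("covariate marginal '%s' does not sum to 1", nm),
           call. = FALSE)
    }
  }
  if (abs(sum(cfg$cause_mixture) - 1) > 1e-8) {
    stop("cause_mixture does not sum to 1", call. = FALSE)
  }
  rm_ <- cfg$risk_model
  eta_max <- log(rm_$baseline_risk)
  worst <- character(0)
  for (v in names(rm_$log_rr)) {
    eff <- rm_$log_rr[[v]]
    best <- which.max(c(0, eff))  # reference level contributes 0
    if (best > 1) {
      eta_max <- eta_max + eff[best - 1]
      worst <- c(worst, paste0(v, "=", names(eff)[best - 1]))
    }
  }
  yr_eff <- rm_$year_log_rr * (length(cfg$years) - 1)
  eta_max <- eta_max + max(0, yr_eff) + 2.5 * rm_$cluster_sd
  if (eta_max > 0) {
    stop(sprintf(
      paste("risk model implies death probability > 1 (%.3f) for covariate",
            "pattern {%s} with the cluster effect at +2.5 SD"),
      exp(eta_max), paste(worst, collapse = ", ")), call. = FALSE)
  }
  invisible(cfg)
}

# truncated-normal draw via inverse CDF (deterministic under the stream seed)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

.draw_levels <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

# Which causes the hierarchical classifier can return for a death with this
# GA and maternal-complication flag (used so latent causes are consistent
# with the records that carry them).
.feasible_causes <- function(ga, mat_comp) {
  term <- ga >= 37
  moderate <- ga >= 34 & ga < 37
  early <- ga < 34
  cbind(congenital_anomaly = TRUE,
        infection = TRUE,
        prematurity = early | (moderate & !mat_comp),
        asphyxia = term | moderate,
        unknown = term)
}

#' Generate a synthetic clustered perinatal registry
#'
#' Produces the three registry tables (maternal, infant, cause-of-death
#' questionnaire) plus the generating truth, fully reproducible from the
#' configured seed. See [simulation_config()] for the generating model.
#'
#' @param config A `simulation_config`.
#' @return List with data frames `maternal`, `infant`, `cod`, and `truth`
#'   (class `true_parameters`): the realized cluster effects, the latent
#'   cause per death, the generating log-RRs and the configuration.
#' @examples
#' reg <- generate_registry(simulation_config(n_clusters = 4, years = 2016,
#'                                            seed = 42))
#' nrow(reg$maternal)
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  stream <- function(k) set.seed(cfg$seed + k)

  ## -- phase 1: structure ---------------------------------------------------
  stream(1L)
  grid <- expand.grid(cluster = seq_len(cfg$n_clusters), year = cfg$years)
  rng <- cfg$deliveries_per_cluster_year
  grid$n <- sample(seq(rng[1], rng[2]), nrow(grid), replace = TRUE)
  n_preg <- sum(grid$n)
  cluster_id <- rep(sprintf("C%02d", grid$cluster), grid$n)
  delivery_year <- rep(grid$year, grid$n)
  mother_id <- sprintf("M%07d", seq_len(n_preg))
  cluster_effect <- .rtruncnorm(cfg$n_clusters, 0, cfg$risk_model$cluster_sd,
                                -2.5 * cfg$risk_model$cluster_sd,
                                2.5 * cfg$risk_model$cluster_sd)
  names(cluster_effect) <- sprintf("C%02d", seq_len(cfg$n_clusters))

  ## -- phase 2: maternal covariates ----------------------------------------
  stream(2L)
  ef <- cfg$exclusion_fractions
  resident <- stats::runif(n_preg) >= ef[["non_resident"]]
  died_pre <- resident & stats::runif(n_preg) < ef[["maternal_death"]]
  mat <- data.frame(mother_id = mother_id, cluster_id = cluster_id,
                    delivery_year = delivery_year,
                    resident_in_cluster = resident,
                    died_before_delivery = died_pre,
                    stringsAsFactors = FALSE)
  for (v in names(cfg$covariate_marginals)) {
    mat[[v]] <- .draw_levels(n_preg, cfg$covariate_marginals[[v]])
  }
  mat$pregnancy_complication <-
    stats::runif(n_preg) < cfg$pregnancy_complication_prob

  ## -- phase 3: pregnancy outcomes, GA, weight ------------------------------
  stream(3L)
  u <- stats::runif(n_preg)
  p_mis <- ef[["miscarriage"]]; p_ter <- ef[["termination"]]
  p_sb <- ef[["stillbirth"]]
  outcome <- ifelse(u < p_mis, "miscarriage",
             ifelse(u < p_mis + p_ter, "medical_termination",
             ifelse(u < p_mis + p_ter + p_sb, "stillbirth", "live_birth")))
  multiple <- stats::runif(n_preg) < cfg$multiple_prob

  gd <- cfg$ga_distribution
  p_pre <- ifelse(multiple, gd$preterm_prob_multiple, gd$preterm_prob)
  is_pre <- stats::runif(n_preg) < p_pre
  ga <- numeric(n_preg)
  n_pre <- sum(is_pre)
  ga[is_pre] <- .rtruncnorm(n_pre, gd$preterm_mean, gd$preterm_sd, 22, 36.99)
  ga[!is_pre] <- .rtruncnorm(n_preg - n_pre, gd$term_mean, gd$term_sd, 37, 44)
  # losses get GA consistent with their label (<20 wk miscarriage/MTP bands)
  ga[outcome == "miscarriage"] <- stats::runif(sum(outcome == "miscarriage"),
                                               6, 19.9)
  ga[outcome == "medical_termination"] <-
    stats::runif(sum(outcome == "medical_termination"), 12, 24)
  ga <- round(ga, 1)

  # one infant row per fetus of a delivered pregnancy (twins share GA)
  delivered <- outcome %in% c("live_birth", "stillbirth")
  n_babies <- ifelse(multiple & delivered, 2L, 1L)
  preg_idx <- rep(seq_len(n_preg), n_babies)
  n_inf <- length(preg_idx)
  wg <- cfg$weight_given_ga
  bw_mean <- wg$mean_at_term + wg$slope_per_week * (ga[preg_idx] - 38.8)
  birth_weight <- round(pmin(pmax(
    stats::rnorm(n_inf, bw_mean, wg$sd), 200), 6000))
  birth_weight[!delivered[preg_idx]] <- NA_real_

  inf <- data.frame(
    infant_id = sprintf("I%07d", seq_len(n_inf)),
    mother_id = mother_id[preg_idx],
    birth_outcome = factor(outcome[preg_idx],
                           levels = registry_enums$birth_outcome),
    birth_weight_g = birth_weight,
    ga_delivery_weeks = ga[preg_idx],
    multiple_gestation = multiple[preg_idx],
    stringsAsFactors = FALSE)

  ## -- phase 4: 28-day deaths ----------------------------------------------
  stream(4L)
  rm_ <- cfg$risk_model
  eta <- rep(log(rm_$baseline_risk), n_inf)
  bw_band <- cut(inf$birth_weight_g, c(-Inf, 1000, 1500, 2500, Inf),
                 right = FALSE,
                 labels = c("lt1000", "1000-1499", "1500-2499", "2500plus"))
  add_effect <- function(eta, values, effects) {
    eff <- effects[as.character(values)]
    eff[is.na(eff)] <- 0
    eta + eff
  }
  for (v in names(rm_$log_rr)) {
    vals <- switch(v,
      bw_category = bw_band,
      mat[[v]][preg_idx])
    eta <- add_effect(eta, vals, rm_$log_rr[[v]])
  }
  eta <- eta + rm_$year_log_rr * (delivery_year[preg_idx] - min(cfg$years))
  eta <- eta + cluster_effect[cluster_id[preg_idx]]
  p_death <- exp(eta)
  if (any(p_death > 1)) {
    stop("realized death probability exceeded 1; reduce risk-model effects",
         call. = FALSE)
  }
  live <- inf$birth_outcome == "live_birth"
  death <- live & stats::runif(n_inf) < p_death
  inf$alive_at_28d <- ifelse(live, !death, NA)
  # death-day distribution concentrated in the first week
  day_probs <- exp(-0.15 * 0:28)
  inf$age_at_death_days <- NA_real_
  inf$age_at_death_days[death] <- sample(0:28, sum(death), replace = TRUE,
                                         prob = day_probs)

  for (v in names(cfg$enc_treatment_rates)) {
    r <- cfg$enc_treatment_rates[[v]]
    pr <- ifelse(death, r[["died"]], r[["alive"]])
    inf[[v]] <- ifelse(live, stats::runif(n_inf) < pr, NA)
  }
  inf$cod_form_available <- NA
  inf$cod_form_available[live] <- TRUE
  inf$cod_form_available[death] <-
    stats::runif(sum(death)) >= cfg$cod_form_missing_prob

  ## -- phase 5: latent causes and questionnaire signs -----------------------
  stream(5L)
  d_idx <- which(death)
  feas <- .feasible_causes(inf$ga_delivery_weeks[d_idx],
                           mat$pregnancy_complication[preg_idx][d_idx])
  mix <- cfg$cause_mixture[colnames(feas)]
  n_d <- length(d_idx)
  latent <- rep(NA_character_, n_d)
  if (n_d > 0) {
    # allocate targets scarcest-feasibility first, so GA-constrained causes
    # (unknown needs term, prematurity needs preterm) reach their share of
    # the target mixture before unconstrained causes absorb those deaths
    target <- round(mix * n_d)
    pool_size <- colSums(feas)
    for (cz in names(sort(pool_size))) {
      open <- which(is.na(latent) & feas[, cz])
      take <- min(target[[cz]], length(open))
      if (take > 0) {
        pick <- if (length(open) == 1) open else sample(open, take)
        latent[pick[seq_len(take)]] <- cz
      }
    }
    # leftovers (rounding, infeasible targets): renormalized mixture draw
    for (i in which(is.na(latent))) {
      w <- mix * feas[i, ]
      latent[i] <- sample(names(mix), 1, prob = w / sum(w))
    }
  }
  emit <- stats::runif(length(d_idx)) < cfg$sign_fidelity
  cod <- data.frame(
    infant_id = inf$infant_id[d_idx],
    major_congenital_anomaly = latent == "congenital_anomaly" & emit,
    tetanus = FALSE, omphalitis = FALSE,
    sepsis = latent == "infection" & emit,
    pneumonia = FALSE, infection_suspected = FALSE,
    ga_delivery_weeks = inf$ga_delivery_weeks[d_idx],
    birth_weight_g = inf$birth_weight_g[d_idx],
    breathing_difficulty_at_birth = latent == "asphyxia" & emit,
    respiratory_distress = FALSE,
    maternal_pregnancy_complication =
      mat$pregnancy_complication[preg_idx][d_idx],
    stringsAsFactors = FALSE)
  cod <- cod[inf$cod_form_available[d_idx] %in% TRUE, , drop = FALSE]
  rownames(cod) <- NULL

  truth <- structure(list(
    config = cfg,
    cluster_effects = cluster_effect,
    log_rr = rm_$log_rr,
    baseline_risk = rm_$baseline_risk,
    cause_mixture = cfg$cause_mixture,
    latent_causes = data.frame(infant_id = inf$infant_id[d_idx],
                               cause = latent, stringsAsFactors = FALSE),
    n_pregnancies = n_preg, n_infants = n_inf,
    n_deaths = length(d_idx),
    mean_death_probability = mean(p_death[live])
  ), class = "true_parameters")

  list(maternal = mat, infant = inf, cod = cod, truth = truth)
}

#' Report the generating values of a synthetic registry
#'
#' Echoes the generating relative risks, baseline risk, cause mixture and
#' cluster-effect scale for use by parameter-recovery tests and audits.
#'
#' @param params A `true_parameters` object.
#' @return List with `rr` (exponentiated generating log-RRs by variable),
#'   `baseline_risk`, `cause_mixture`, `cluster_sd`, and realized counts.
#' @export
summarize_truth <- function(params) {
  stopifnot(inherits(params, "true_parameters"))
  list(
    rr = lapply(params$log_rr, exp),
    baseline_risk = params$baseline_risk,
    cause_mixture = params$cause_mixture,
    cluster_sd = params$config$risk_model$cluster_sd,
    realized_cluster_effect_sd = stats::sd(params$cluster_effects),
    n_pregnancies = params$n_pregnancies,
    n_infants = params$n_infants,
    n_deaths = params$n_deaths,
    mean_death_probability = params$mean_death_probability
  )
}

#' Write a generated registry to CSV files
#'
#' @param registry Output of [generate_registry()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths.
#' @export
write_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  schema <- registry_schema()
  paths <- c(maternal = file.path(dir, "maternal.csv"),
             infant = file.path(dir, "infant.csv"),
             cod = file.path(dir, "cod.csv"))
  write_registry_csv(registry$maternal[schema$maternal$columns],
                     paths[["maternal"]])
  write_registry_csv(registry$infant[schema$infant$columns],
                     paths[["infant"]])
  write_registry_csv(registry$cod[schema$cod$columns], paths[["cod"]])
  paths
}
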