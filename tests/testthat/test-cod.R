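test_that("hierarchy examples assign as specified", {
  expect_equal(assign_cause(list(major_congenital_anomaly = TRUE,
                                 sepsis = TRUE,
                                 ga_delivery_weeks = 28))$cause,
               "congenital_anomaly")
  expect_equal(assign_cause(list(ga_delivery_weeks = 39,
                                 breathing_difficulty_at_birth = FALSE))$cause,
               "unknown")
  expect_equal(assign_cause(list(ga_delivery_weeks = 30,
                                 birth_weight_g = 1200))$cause, "prematurity")
  expect_equal(assign_cause(list(ga_delivery_weeks = 35,
                                 maternal_pregnancy_complication = TRUE))$cause,
               "asphyxia")
  expect_equal(assign_cause(list(ga_delivery_weeks = 38,
                                 respiratory_distress = TRUE))$cause,
               "asphyxia")
})

test_that("record with neither GA nor weight is unknown with a warning", {
  expect_warning(res <- assign_cause(list(sepsis = FALSE)), "neither")
  expect_equal(res$cause, "unknown")
})

test_that("anomaly dominates all other fields (property)", {
  set.seed(42)
  for (i in 1:60) {
    input <- list(major_congenital_anomaly = TRUE,
                  tetanus = runif(1) < .5, omphalitis = runif(1) < .5,
                  sepsis = runif(1) < .5, pneumonia = runif(1) < .5,
                  infection_suspected = runif(1) < .5,
                  breathing_difficulty_at_birth = runif(1) < .5,
                  respiratory_distress = runif(1) < .5,
                  maternal_pregnancy_complication = runif(1) < .5,
                  ga_delivery_weeks = sample(c(NA, runif(1, 22, 43)), 1),
                  birth_weight_g = sample(c(NA, runif(1, 400, 4500)), 1))
    expect_equal(assign_cause(input)$cause, "congenital_anomaly")
  }
})

test_that("infection dominates GA-based causes when anomaly absent (property)", {
  set.seed(43)
  signs <- c("tetanus", "omphalitis", "sepsis", "pneumonia",
             "infection_suspected")
  for (i in 1:40) {
    input <- list(ga_delivery_weeks = runif(1, 22, 43),
                  breathing_difficulty_at_birth = runif(1) < .5,
                  maternal_pregnancy_complication = runif(1) < .5)
    input[[sample(signs, 1)]] <- TRUE
    expect_equal(assign_cause(input)$cause, "infection")
  }
})

test_that("term boundary is monotone: 37 weeks unknown, 33 weeks prematurity", {
  base <- list(breathing_difficulty_at_birth = FALSE,
               respiratory_distress = FALSE,
               maternal_pregnancy_complication = FALSE)
  expect_equal(assign_cause(c(base, ga_delivery_weeks = 37))$cause, "unknown")
  expect_equal(assign_cause(c(base, ga_delivery_weeks = 36.9))$cause,
               "prematurity")
  expect_equal(assign_cause(c(base, ga_delivery_weeks = 33))$cause,
               "prematurity")
})

test_that("classifier matches the independent nested-if oracle on a factorial grid", {
  flags <- expand.grid(anomaly = c(FALSE, TRUE), infection = c(FALSE, TRUE),
                       breath = c(FALSE, TRUE), distress = c(FALSE, TRUE),
                       matcomp = c(FALSE, TRUE),
                       ga = c(28, 35, 39, NA),
                       wt = c(1500, 2200, 3000, NA))
  flags <- flags[!(is.na(flags$ga) & is.na(flags$wt)), ]
  grid <- data.frame(
    major_congenital_anomaly = flags$anomaly,
    tetanus = FALSE, omphalitis = FALSE, sepsis = flags$infection,
    pneumonia = FALSE, infection_suspected = FALSE,
    ga_delivery_weeks = flags$ga, birth_weight_g = flags$wt,
    breathing_difficulty_at_birth = flags$breath,
    respiratory_distress = flags$distress,
    maternal_pregnancy_complication = flags$matcomp)
  got <- classify_deaths(grid)$assignments$cause
  want <- mapply(function(a, s, b, d, m, g, w)
    cod_oracle(anomaly = a, sepsis = s, breath = b, distress = d,
               matcomp = m, ga = g, wt = w),
    flags$anomaly, flags$infection, flags$breath, flags$distress,
    flags$matcomp, flags$ga, flags$wt)
  expect_equal(as.character(got), unname(want))
})

test_that("classifier matches oracle with infection signs varied individually", {
  signs <- c("tetanus", "omphalitis", "sepsis", "pneumonia",
             "infection_suspected")
  for (s in signs) {
    input <- list(ga_delivery_weeks = 39)
    input[[s]] <- TRUE
    expect_equal(assign_cause(input)$cause, "infection", info = s)
  }
})

test_that("tally conserves the number of deaths and rules are audited", {
  reg <- generate_registry(desk_config(seed = 5, n_clusters = 10))
  res <- classify_deaths(reg$cod)
  expect_equal(sum(res$tally), nrow(reg$cod))
  expect_false(any(is.na(res$assignments$cause)))
  expect_true(all(res$assignments$rule %in% c(
    "anomaly", "infection", "term_asphyxia", "term_no_signs",
    "moderate_asphyxia", "early_prematurity", "moderate_preterm_residual",
    "missing_ga_and_weight", "unassigned")))
})

test_that("classifier recovers latent causes exactly at sign fidelity 1", {
  cfg <- desk_config(seed = 31, n_clusters = 12, sign_fidelity = 1.0,
                     cod_form_missing_prob = 0)
  reg <- generate_registry(cfg)
  res <- classify_deaths(reg$cod)
  truth <- reg$truth$latent_causes
  m <- merge(res$assignments[c("infant_id", "cause")], truth,
             by = "infant_id", suffixes = c("_hat", "_true"))
  expect_gt(nrow(m), 30)
  expect_equal(as.character(m$cause_hat), m$cause_true)
})

test_that("recovery degrades no faster than the configured fidelity", {
  cfg <- desk_config(seed = 32, n_clusters = 12, years = 2015:2016,
                     sign_fidelity = 0.9, cod_form_missing_prob = 0)
  reg <- generate_registry(cfg)
  res <- classify_deaths(reg$cod)
  m <- merge(res$assignments[c("infant_id", "cause")],
             reg$truth$latent_causes, by = "infant_id",
             suffixes = c("_hat", "_true"))
  acc <- mean(as.character(m$cause_hat) == m$cause_true)
  n <- nrow(m)
  # overall accuracy can exceed fidelity (some misses still classify right);
  # it must not fall below fidelity by more than binomial error
  expect_gt(acc, 0.9 - 3 * sqrt(0.9 * 0.1 / n))
})
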