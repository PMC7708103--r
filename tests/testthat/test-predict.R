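test_that("intercept-only fit reproduces the crude risk", {
  reg <- generate_registry(desk_config(seed = 41, n_clusters = 10))
  co <- build_cohort(reg$maternal, reg$infant)
  res <- fit_multivariable(co, character(0))
  crude <- mean(co$data$death_28d)
  expect_equal(exp(unname(coef(res$fit)[1])), crude, tolerance = 1e-6)
  expect_equal(res$marginal_r2, 0, tolerance = 1e-12)
})

test_that("marginal R-squared is 1 for a perfect fit and bounded in [0,1]", {
  fit <- list(y = c(0, 1, 0, 1), fitted = c(0, 1, 0, 1))
  class(fit) <- "gee_fit"
  expect_equal(marginal_r2(fit), 1)
  fit$fitted <- rep(0.5, 4)
  expect_equal(marginal_r2(fit), 0)
  fit$y <- rep(1, 4)
  expect_warning(r <- marginal_r2(fit), "zero variance")
  expect_true(is.na(r))
})

test_that("marginal R-squared does not decrease when a predictive variable is added", {
  reg <- generate_registry(desk_config(seed = 44, n_clusters = 20,
                                       years = 2015:2016))
  co <- build_cohort(reg$maternal, reg$infant)
  r0 <- fit_multivariable(co, "education")$marginal_r2
  r1 <- fit_multivariable(co, c("education", "bw_category"))$marginal_r2
  expect_gte(r1, r0)
})

test_that("QIC is deterministic and penalizes pure-noise covariates", {
  reg <- generate_registry(desk_config(seed = 45, n_clusters = 15))
  co <- build_cohort(reg$maternal, reg$infant)
  f1 <- fit_multivariable(co, "bw_category")
  f2 <- fit_multivariable(co, "bw_category")
  expect_identical(qic(f1$fit), qic(f2$fit))

  set.seed(46)
  n_reps <- 100
  delta <- numeric(n_reps)
  base_qic <- qic(f1$fit)
  d <- co$data
  for (i in seq_len(n_reps)) {
    d$noise <- rnorm(nrow(d))
    fn <- fit_multivariable(d, c("bw_category", "noise"))
    delta[i] <- qic(fn$fit) - base_qic
  }
  # a 1-df noise term raises QIC with probability P(chisq_1 < 2) ~ 0.84;
  # assert the penalty property with room for binomial noise at 100 reps
  expect_gte(mean(delta > 0), 0.75)
  expect_gt(mean(delta), 0)
})

test_that("QIC approaches the classical information criterion on independent data", {
  set.seed(47)
  n <- 500
  d <- data.frame(cluster_id = sprintf("U%04d", 1:n),
                  x = rnorm(n))
  d$death_28d <- runif(n) < exp(-2.5 + 0.4 * d$x)
  fit <- gee_fit(death_28d ~ x, d, family = "binomial")
  oracle <- glm(death_28d ~ x, data = d, family = binomial(link = "log"),
                start = coef(fit))
  expect_lt(abs(qic(fit) - AIC(oracle)) / AIC(oracle), 0.02)
})

test_that("forward selection with a single strong candidate yields a path of length 1", {
  cfg <- desk_config(seed = 48, n_clusters = 15,
    risk_model = list(baseline_risk = 0.01,
                      log_rr = list(bw_category = c(`lt1000` = 2.5,
                                                    `1000-1499` = 2.2,
                                                    `1500-2499` = 1.2)),
                      cluster_sd = 0.15, year_log_rr = 0))
  reg <- generate_registry(cfg)
  co <- build_cohort(reg$maternal, reg$infant)
  sel <- forward_select(co, "bw_category")
  expect_equal(sel$selected, "bw_category")
  expect_equal(nrow(sel$steps), 1)
  # QIC is monotone non-increasing along the path
  expect_true(all(sel$steps$qic_after <= sel$steps$qic_before))
})

test_that("selection path is stable under candidate permutation without ties", {
  cfg <- desk_config(seed = 49, n_clusters = 15,
    risk_model = list(baseline_risk = 0.01,
                      log_rr = list(bw_category = c(`lt1000` = 2.5,
                                                    `1000-1499` = 2.2,
                                                    `1500-2499` = 1.2)),
                      cluster_sd = 0.15, year_log_rr = 0))
  reg <- generate_registry(cfg)
  co <- build_cohort(reg$maternal, reg$infant)
  cands <- c("bw_category", "education", "parity_category")
  s1 <- forward_select(co, cands)
  s2 <- forward_select(co, rev(cands))
  expect_setequal(s1$selected, s2$selected)
  expect_equal(s1$steps$added[1], "bw_category")
  expect_equal(s2$steps$added[1], "bw_category")
})

test_that("multivariable fit recovers generating effects and orders birth-weight RRs", {
  cfg <- desk_config(seed = 50, n_clusters = 20, years = 2015:2016,
    risk_model = list(baseline_risk = 0.008,
                      log_rr = list(
                        bw_category = c(`lt1000` = 3.0, `1000-1499` = 2.6,
                                        `1500-2499` = 1.1),
                        anc_visits_category = c(`0-1` = 0.45, `2` = 0.3,
                                                `3` = 0.15)),
                      cluster_sd = 0.15, year_log_rr = 0))
  reg <- generate_registry(cfg)
  co <- build_cohort(reg$maternal, reg$infant)
  res <- fit_multivariable(co, c("bw_category", "anc_visits_category"))
  s <- res$summary
  rr <- setNames(s$rr, s$term)
  expect_gt(rr[["bw_categorylt1000"]], rr[["bw_category1000-1499"]])
  expect_gt(rr[["bw_category1000-1499"]], rr[["bw_category1500-2499"]])
  expect_gt(rr[["bw_category1500-2499"]], 1)
  # generating values inside their 95% CIs for the strong effects
  ci <- s[s$term == "bw_categorylt1000", ]
  expect_gt(exp(3.0), ci$ci_low)
  expect_lt(exp(3.0), ci$ci_high)
  expect_true(res$marginal_r2 > 0 && res$marginal_r2 < 1)
})

test_that("marginal R-squared of the preset model sits in its snapshot band", {
  # regression snapshot under the default generating model (its effect sizes
  # are milder than a real registry's, so explained variability is modest)
  cfg <- desk_config(seed = 52, n_clusters = 12, years = 2015:2016)
  reg <- generate_registry(cfg)
  co <- build_cohort(reg$maternal, reg$infant)
  res <- fit_multivariable(co, predictive_model_preset())
  expect_gt(res$marginal_r2, 0.02)
  expect_lt(res$marginal_r2, 0.25)
})

test_that("collinear design columns are dropped with a warning", {
  reg <- generate_registry(desk_config(seed = 51, n_clusters = 8))
  co <- build_cohort(reg$maternal, reg$infant)
  d <- co$data
  d$dup <- -d$ga_weeks_decrease  # alias of ga_delivery_weeks
  d$ga_copy <- d$ga_weeks_decrease
  expect_warning(
    fit <- gee_fit(death_28d ~ ga_weeks_decrease + ga_copy, d,
                   family = "poisson"),
    "aliased")
  expect_false("ga_copy" %in% fit$xnames)
})
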