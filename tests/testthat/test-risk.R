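test_that("crude RR reproduces the printed closed-form estimates", {
  expect_equal(round(crude_rr(two_by_two(364, 3235, 394, 27708))$rr, 2), 7.91)
  expect_equal(round(crude_rr(two_by_two(75, 572, 683, 30371))$rr, 2), 5.83)
  expect_equal(round(crude_rr(two_by_two(69, 2106, 360, 16921))$rr, 2), 1.54)
  expect_equal(round(crude_rr(two_by_two(329, 11914, 360, 16921))$rr, 2), 1.30)
})

test_that("symmetric table gives RR 1 with CI spanning 1", {
  est <- crude_rr(two_by_two(10, 100, 10, 100))
  expect_equal(est$rr, 1)
  expect_lt(est$ci_low, 1)
  expect_gt(est$ci_high, 1)
})

test_that("crude RR of a level against itself is exactly 1", {
  est <- crude_rr(two_by_two(360, 16921, 360, 16921))
  expect_identical(est$rr, 1)
})

test_that("scaling all cells preserves RR and narrows the CI", {
  e1 <- crude_rr(two_by_two(20, 200, 15, 300))
  e4 <- crude_rr(two_by_two(80, 800, 60, 1200))
  expect_equal(e4$rr, e1$rr)
  expect_lt(e4$ci_high - e4$ci_low, e1$ci_high - e1$ci_low)
})

test_that("zero cells are flagged rather than raised", {
  est <- crude_rr(two_by_two(0, 50, 5, 100))
  expect_true(est$unbounded_ci)
  est2 <- crude_rr(two_by_two(5, 50, 0, 100))
  expect_true(est2$unbounded_ci)
  expect_true(is.infinite(est2$ci_high) || is.na(est2$ci_high))
})

test_that("Wald CI agrees with a nonparametric bootstrap oracle", {
  tab <- two_by_two(75, 572, 683, 30371)
  est <- crude_rr(tab)
  expect_equal(round(est$rr, 2), 5.83)
  set.seed(1234)
  reps <- 10000
  a_b <- rbinom(reps, tab$n1, tab$a / tab$n1)
  c_b <- rbinom(reps, tab$n0, tab$c / tab$n0)
  rr_b <- (a_b / tab$n1) / (c_b / tab$n0)
  boot_ci <- quantile(rr_b, c(0.025, 0.975))
  # Wald and bootstrap intervals agree to a few percent at these counts
  expect_lt(abs(est$ci_low - boot_ci[[1]]) / boot_ci[[1]], 0.05)
  expect_lt(abs(est$ci_high - boot_ci[[2]]) / boot_ci[[2]], 0.05)
})

test_that("cluster_rr equals the non-clustered ML fit when all clusters have size 1", {
  set.seed(77)
  n <- 3000
  d <- data.frame(cluster_id = sprintf("S%04d", 1:n),
                  exposure = factor(sample(c("ref", "exp"), n, TRUE,
                                           prob = c(.7, .3)),
                                    levels = c("ref", "exp")))
  d$death_28d <- runif(n) < ifelse(d$exposure == "exp", 0.06, 0.02)
  res <- cluster_rr(d, "exposure", reference = "ref")
  fit_ml <- glm(death_28d ~ exposure, data = d,
                family = binomial(link = "log"),
                start = log(c(0.02, 3)))
  rr_ml <- exp(coef(fit_ml)[["exposureexp"]])
  expect_equal(res$estimates$exp$rr, rr_ml, tolerance = 1e-6)
})

test_that("robust variance matches an independent cluster-robust GLM oracle", {
  skip_if_not_installed("sandwich")
  reg <- generate_registry(desk_config(seed = 21, n_clusters = 15))
  co <- build_cohort(reg$maternal, reg$infant)
  d <- co$data[!is.na(co$data$education), ]
  fit <- gee_fit(death_28d ~ education, d, family = "poisson")
  g <- glm(death_28d ~ education, data = d, family = poisson(link = "log"))
  v <- sandwich::vcovCL(g, cluster = d$cluster_id, cadjust = FALSE)
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(diag(vcov(fit))), unname(diag(v)), tolerance = 1e-6)
})

test_that("single-cluster input is rejected with advice", {
  d <- data.frame(cluster_id = "C01",
                  exposure = factor(rep(c("a", "b"), 50)),
                  death_28d = rep(c(TRUE, FALSE), c(10, 90)))
  expect_error(cluster_rr(d, "exposure"), "2 clusters")
})

test_that("crude and cluster-adjusted estimates agree with no cluster variance", {
  cfg <- desk_config(seed = 2718, n_clusters = 20,
                     risk_model = single_effect_risk(log(2.5),
                                                     cluster_sd = 0))
  reg <- generate_registry(cfg)
  co <- build_cohort(reg$maternal, reg$infant)
  d <- co$data[!is.na(co$data$education), ]
  # compare at the level actually contrasted: no_formal vs university_plus
  keep <- d$education %in% c("no_formal", "university_plus")
  dd <- d[keep, ]
  tab <- cohort_two_by_two(dd, dd$education == "no_formal")
  cr <- crude_rr(tab)
  res <- cluster_rr(d, "education", reference = "university_plus")
  expect_equal(res$estimates$no_formal$rr, cr$rr, tolerance = 0.01)
})

test_that("continuous RR is sign-symmetric and flags constant input", {
  reg <- generate_registry(desk_config(seed = 12, n_clusters = 10))
  co <- build_cohort(reg$maternal, reg$infant)
  e_dec <- continuous_rr(co, "ga_delivery_weeks", per_unit_decrease = TRUE)
  d <- co$data
  d$neg_ga <- -d$ga_delivery_weeks
  e_neg <- continuous_rr(d, "neg_ga", per_unit_decrease = FALSE)
  expect_equal(e_dec$rr, e_neg$rr, tolerance = 1e-10)
  expect_gt(e_dec$rr, 1)  # lower GA carries higher risk by construction
  d$const <- 1
  expect_error(continuous_rr(d, "const"), "constant")
})

test_that("continuous RR is near 1 for an effectless variable", {
  cfg <- desk_config(seed = 13, n_clusters = 20,
                     risk_model = single_effect_risk(0, cluster_sd = 0.1))
  reg <- generate_registry(cfg)
  co <- build_cohort(reg$maternal, reg$infant)
  d <- co$data
  set.seed(99)
  d$noise <- rnorm(nrow(d))
  est <- continuous_rr(d, "noise")
  expect_lt(est$ci_low, 1)
  expect_gt(est$ci_high, 1)
})

test_that("exchangeable working correlation is accepted and near independence here", {
  reg <- generate_registry(desk_config(seed = 14, n_clusters = 12))
  co <- build_cohort(reg$maternal, reg$infant)
  r_ind <- cluster_rr(co$data, "parity_category", reference = "1-2")
  r_exc <- cluster_rr(co$data, "parity_category", reference = "1-2",
                      corstr = "exchangeable")
  expect_equal(r_exc$estimates$`0`$rr, r_ind$estimates$`0`$rr,
               tolerance = 0.05)
  expect_true(is.finite(r_exc$fit$alpha))
})
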