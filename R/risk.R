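# Relative risks of 28-day neonatal death: closed-form crude estimates from
# 2x2 tables, and cluster-adjusted estimates from log-link marginal models
# with robust variance (one exposure variable at a time, complete case per
# exposure, matching how registry risk-factor tables are built).

#' Two-by-two exposure table
#'
#' @param a Events among exposed.
#' @param n1 Exposed total.
#' @param c Events among unexposed.
#' @param n0 Unexposed total.
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(a, n1, c, n0) {
  stopifnot(a >= 0, c >= 0, n1 >= a, n0 >= c)
  structure(list(a = a, n1 = n1, c = c, n0 = n0), class = "two_by_two")
}

.risk_estimate <- function(rr, ci_low, ci_high, p_value, method, level = NA,
                           reference = NA, n = NA, unbounded_ci = FALSE) {
  structure(list(rr = rr, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, method = method, level = level,
                 reference = reference, n = n, unbounded_ci = unbounded_ci),
            class = "risk_estimate")
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("RR %.2f (95%% CI %.2f, %.2f), p = %.4g [%s]\n",
              x$rr, x$ci_low, x$ci_high, x$p_value, x$method))
  invisible(x)
}

#' Crude relative risk from a 2x2 table
#'
#' Closed-form risk ratio `(a/n1) / (c/n0)` with the standard log-scale Wald
#' 95% interval, `exp(log RR +/- 1.96 * sqrt(1/a - 1/n1 + 1/c - 1/n0))`, and
#' a two-sided Wald p-value. Zero event cells yield an undefined RR or an
#' unbounded interval, returned flagged rather than as an error.
#'
#' @param table A [two_by_two()] object.
#' @return A `risk_estimate` with method `"crude"`.
#' @examples
#' crude_rr(two_by_two(364, 3235, 394, 27708))  # preterm vs term
#' @export
crude_rr <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  a <- table$a; n1 <- table$n1; c <- table$c; n0 <- table$n0
  stopifnot(n1 > 0, n0 > 0)
  if (a == 0 && c == 0) {
    return(.risk_estimate(NA_real_, NA_real_, NA_real_, NA_real_, "crude",
                          n = n1 + n0, unbounded_ci = TRUE))
  }
  rr <- (a / n1) / (c / n0)
  if (a == 0 || c == 0) {
    return(.risk_estimate(rr, if (c == 0) NA else 0,
                          if (c == 0) Inf else NA, NA_real_, "crude",
                          n = n1 + n0, unbounded_ci = TRUE))
  }
  se <- sqrt(1 / a - 1 / n1 + 1 / c - 1 / n0)
  z <- log(rr) / se
  .risk_estimate(rr, exp(log(rr) - .Z975 * se), exp(log(rr) + .Z975 * se),
                 2 * stats::pnorm(-abs(z)), "crude", n = n1 + n0)
}

#' Cluster-adjusted relative risks for a categorical exposure
#'
#' Fits a log-link marginal model of 28-day death on the exposure's
#' indicator contrasts with robust variance clustered on study cluster
#' ([gee_fit()]), returning one relative risk per non-reference level plus a
#' joint Wald test across levels (the per-variable p-value of registry
#' risk-factor tables).
#'
#' @param cohort An `analysis_cohort` or a data frame with `death_28d` and
#'   `cluster_id`.
#' @param exposure Name of a categorical column.
#' @param reference Reference level (default: first level of the factor).
#' @param corstr Working correlation passed to [gee_fit()].
#' @return List with `estimates` (one `risk_estimate` per non-reference
#'   level), `joint_wald` (statistic, df, p), `fit` (the `gee_fit`), and `n`.
#' @export
cluster_rr <- function(cohort, exposure, reference = NULL,
                       corstr = "independence") {
  d <- if (inherits(cohort, "analysis_cohort")) cohort$data else cohort
  if (!exposure %in% names(d)) {
    stop(sprintf("unknown exposure '%s'", exposure), call. = FALSE)
  }
  v <- d[[exposure]]
  if (is.logical(v)) v <- factor(v, levels = c(FALSE, TRUE),
                                 labels = c("no", "yes"))
  if (!is.factor(v)) v <- factor(v)
  if (!is.null(reference)) {
    if (!reference %in% levels(v)) {
      stop(sprintf("reference level '%s' not a level of '%s'", reference,
                   exposure), call. = FALSE)
    }
    v <- stats::relevel(v, ref = reference)
  }
  d$.exposure <- v
  fit <- gee_fit(death_28d ~ .exposure, d, cluster = "cluster_id",
                 family = "binomial", corstr = corstr)
  terms <- setdiff(fit$xnames, "(Intercept)")
  se <- sqrt(diag(fit$vcov))
  method <- if (fit$variance_used == "binomial") "cluster_gee" else
    "cluster_gee_poisson"
  ests <- lapply(terms, function(tm) {
    b <- unname(fit$coefficients[tm]); s <- unname(se[tm])
    .risk_estimate(exp(b), exp(b - .Z975 * s), exp(b + .Z975 * s),
                   2 * stats::pnorm(-abs(b / s)), method,
                   level = sub("^\\.exposure", "", tm),
                   reference = levels(v)[1], n = fit$n)
  })
  names(ests) <- sub("^\\.exposure", "", terms)
  list(estimates = ests, joint_wald = .wald_test(fit, terms), fit = fit,
       n = fit$n)
}

#' Relative risk per unit change of a continuous variable
#'
#' Log-link marginal model with a single continuous covariate. With
#' `per_unit_decrease = TRUE` the variable is negated before fitting, so an
#' RR above 1 means risk rises as the variable falls (e.g. risk per one-week
#' decrease in gestational age).
#'
#' @param cohort An `analysis_cohort` or data frame.
#' @param variable Numeric column name.
#' @param per_unit_decrease Report the risk ratio per unit decrease.
#' @param corstr Working correlation.
#' @return A `risk_estimate` (with the underlying `gee_fit` as attribute
#'   `"fit"`).
#' @export
continuous_rr <- function(cohort, variable, per_unit_decrease = FALSE,
                          corstr = "independence") {
  d <- if (inherits(cohort, "analysis_cohort")) cohort$data else cohort
  if (!variable %in% names(d)) {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  x <- d[[variable]]
  if (!is.numeric(x)) stop(sprintf("'%s' is not numeric", variable),
                           call. = FALSE)
  if (stats::var(x, na.rm = TRUE) == 0 || all(is.na(x))) {
    stop(sprintf("'%s' is constant; no risk gradient estimable", variable),
         call. = FALSE)
  }
  d$.x <- if (per_unit_decrease) -x else x
  fit <- gee_fit(death_28d ~ .x, d, cluster = "cluster_id",
                 family = "binomial", corstr = corstr)
  b <- unname(fit$coefficients[".x"])
  s <- sqrt(fit$vcov[".x", ".x"])
  method <- if (fit$variance_used == "binomial") "cluster_gee" else
    "cluster_gee_poisson"
  est <- .risk_estimate(exp(b), exp(b - .Z975 * s), exp(b + .Z975 * s),
                        2 * stats::pnorm(-abs(b / s)), method, n = fit$n)
  attr(est, "fit") <- fit
  est
}

#' Tidy table of risk estimates for several exposures
#'
#' Convenience wrapper running [cluster_rr()] (categorical) or
#' [continuous_rr()] (numeric) over a list of exposure variables.
#'
#' @param cohort An `analysis_cohort`.
#' @param variables Character vector of exposure columns.
#' @param references Optional named list of reference levels.
#' @return Data frame: variable, level, reference, rr, ci_low, ci_high, p,
#'   joint Wald p per variable, method, n.
#' @export
risk_table <- function(cohort, variables, references = list()) {
  rows <- list()
  d <- cohort$data
  for (v in variables) {
    if (is.numeric(d[[v]])) {
      est <- continuous_rr(cohort, v, per_unit_decrease = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = "per unit decrease", reference = NA,
        rr = est$rr, ci_low = est$ci_low, ci_high = est$ci_high,
        p = est$p_value, joint_p = est$p_value, method = est$method,
        n = est$n, stringsAsFactors = FALSE)
    } else {
      res <- cluster_rr(cohort, v, reference = references[[v]])
      for (lv in names(res$estimates)) {
        e <- res$estimates[[lv]]
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = lv, reference = e$reference, rr = e$rr,
          ci_low = e$ci_low, ci_high = e$ci_high, p = e$p_value,
          joint_p = res$joint_wald$p_value, method = e$method, n = e$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
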