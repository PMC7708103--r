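# Multivariable predictive model of 28-day neonatal death: log-link,
# count-variance (modified Poisson) marginal model with robust clustered
# variance, forward selection under the quasi-likelihood independence-model
# criterion (QIC), and a squared-error marginal R-squared of the fitted
# marginal mean.

#' Fit the multivariable predictive model
#'
#' Log-link marginal model of the binary death indicator with Poisson
#' (count) variance and robust variance clustered on study cluster, so the
#' exponentiated coefficients are adjusted relative risks. Collinear design
#' columns are dropped with a warning.
#'
#' @param cohort An `analysis_cohort` or data frame with `death_28d` and
#'   `cluster_id`.
#' @param variables Character vector of model variables (factors or numeric).
#' @param corstr Working correlation.
#' @return List with `fit` (a `gee_fit`), `summary` (data frame of adjusted
#'   RRs with 95% CIs and p-values) and `marginal_r2`.
#' @export
fit_multivariable <- function(cohort, variables, corstr = "independence") {
  d <- if (inherits(cohort, "analysis_cohort")) cohort$data else cohort
  missing_vars <- setdiff(variables, names(d))
  if (length(missing_vars)) {
    stop("unknown variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  rhs <- if (length(variables)) paste(variables, collapse = " + ") else "1"
  f <- stats::as.formula(paste("death_28d ~", rhs))
  fit <- gee_fit(f, d, cluster = "cluster_id", family = "poisson",
                 corstr = corstr)
  se <- sqrt(diag(fit$vcov))
  terms <- setdiff(fit$xnames, "(Intercept)")
  summ <- data.frame(
    term = terms, rr = exp(fit$coefficients[terms]),
    ci_low = exp(fit$coefficients[terms] - .Z975 * se[terms]),
    ci_high = exp(fit$coefficients[terms] + .Z975 * se[terms]),
    p = 2 * stats::pnorm(-abs(fit$coefficients[terms] / se[terms])),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(fit = fit, summary = summ, marginal_r2 = marginal_r2(fit))
}

#' Quasi-likelihood under the independence model criterion (QIC)
#'
#' `QIC = -2 * QL(mu; independence) + 2 * trace(Omega %*% V)`, where `QL` is
#' the quasi-likelihood of the fitted means evaluated under the independence
#' working model, `Omega` the model-based information under independence and
#' `V` the robust covariance. On truly independent, correctly specified data
#' the penalty approaches `2p` and QIC approaches the classical information
#' criterion.
#'
#' @param fit A `gee_fit`.
#' @return The QIC value (scalar).
#' @export
qic <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!fit$converged) stop("QIC undefined: fit did not converge",
                           call. = FALSE)
  pen <- tryCatch(sum(diag(fit$omega %*% fit$vcov)), error = function(e) NA)
  if (!is.finite(pen)) {
    kappa_cols <- fit$xnames[!is.finite(diag(fit$omega))]
    stop("singular information matrix in QIC; deficient term(s): ",
         paste(kappa_cols, collapse = ", "), call. = FALSE)
  }
  -2 * fit$quasi_lik + 2 * pen
}

#' Marginal R-squared of a fitted marginal model
#'
#' Squared-error form: `1 - sum((y - mu)^2) / sum((y - ybar)^2)` over all
#' analysis records, i.e. the proportion of outcome variability explained by
#' the fitted marginal mean. Exactly 0 for an intercept-only model and 1 for
#' a saturated fit.
#'
#' @param fit A `gee_fit` with intercept.
#' @return Scalar in `[0, 1]` for any model containing an intercept.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  y <- fit$y
  mu <- fit$fitted
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("outcome has zero variance; marginal R-squared undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - sum((y - mu)^2) / sst
}

#' Forward selection of predictive variables by QIC
#'
#' Greedy forward selection: starting from the intercept-only model, each
#' step adds the candidate variable that minimizes QIC; selection stops when
#' no addition lowers QIC. Ties break deterministically by candidate list
#' order. A candidate whose fit fails is disqualified with a warning.
#'
#' @param cohort An `analysis_cohort` or data frame.
#' @param candidates Character vector of candidate variables.
#' @param corstr Working correlation.
#' @return A `selection_path`: list with `steps` (data frame of chosen
#'   variable and QIC before/after per step), `selected` (final variable
#'   set), `final` (the [fit_multivariable()] result for the final set).
#' @export
forward_select <- function(cohort, candidates, corstr = "independence") {
  selected <- character(0)
  current <- fit_multivariable(cohort, selected, corstr = corstr)
  current_qic <- qic(current$fit)
  steps <- list()
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    qics <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      cand_fit <- tryCatch(
        fit_multivariable(cohort, c(selected, remaining[i]), corstr = corstr),
        error = function(e) {
          warning(sprintf("candidate '%s' disqualified: %s", remaining[i],
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (!is.null(cand_fit)) {
        qics[i] <- tryCatch(qic(cand_fit$fit), error = function(e) NA_real_)
      }
    }
    if (all(is.na(qics))) break
    best <- which.min(replace(qics, is.na(qics), Inf))  # first minimum wins
    if (qics[best] >= current_qic) break
    steps[[length(steps) + 1]] <- data.frame(
      step = length(steps) + 1, added = remaining[best],
      qic_before = current_qic, qic_after = qics[best],
      stringsAsFactors = FALSE)
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    current_qic <- qics[best]
  }
  final <- fit_multivariable(cohort, selected, corstr = corstr)
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(step = integer(0), added = character(0),
                 qic_before = numeric(0), qic_after = numeric(0)),
    selected = selected, final = final,
    intercept_qic = qic(fit_multivariable(cohort, character(0),
                                          corstr = corstr)$fit)
  ), class = "selection_path")
}

#' @export
print.selection_path <- function(x, ...) {
  cat("QIC forward selection\n")
  cat(sprintf("  intercept-only QIC: %.2f\n", x$intercept_qic))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      cat(sprintf("  + %-24s QIC %.2f -> %.2f\n", x$steps$added[i],
                  x$steps$qic_before[i], x$steps$qic_after[i]))
    }
  } else cat("  no variable improved QIC; intercept-only model kept\n")
  cat(sprintf("  final model: %s (marginal R-squared %.3f)\n",
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "intercept only", x$final$marginal_r2))
  invisible(x)
}

#' Default candidate variables and the shipped final-model preset
#'
#' The default predictive candidates are the maternal and neonatal
#' characteristics; essential-newborn-care and treatment variables are
#' excluded because their occurrence is a consequence of the infant's
#' condition rather than an antecedent risk factor. The preset
#' (`predictive_model_preset()`) is the three-variable final model
#' (gestational age at delivery, birth-weight category, antenatal care
#' visits) so the same model structure can be refitted on any dataset.
#'
#' @return Character vector of variable names.
#' @export
predictive_candidates <- function() {
  c("bw_category", "ga_weeks_decrease", "anc_visits_category",
    "parity_category", "education", "multiple_gestation", "preterm")
}

#' @rdname predictive_candidates
#' @export
predictive_model_preset <- function() {
  c("ga_weeks_decrease", "bw_category", "anc_visits_category")
}
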