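# Rates and distributions: neonatal mortality rate per 1000 live births,
# cause-of-death distribution, and categorical variable tables split by
# 28-day vital status. Printed values use half-up rounding to one decimal,
# matching epidemiological reporting convention; internal values keep full
# precision.

#' Half-up rounding
#'
#' Rounds halves away from zero (the convention of printed epidemiological
#' tables), unlike [round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

.rate_row <- function(num, den, stratum) {
  rate <- if (den > 0) 1000 * num / den else NA_real_
  if (den == 0) warning(sprintf(
    "stratum '%s': zero live births, rate undefined", stratum), call. = FALSE)
  data.frame(stratum = stratum, deaths = num, live_births = den,
             rate_per_1000 = rate,
             rate_printed = round_half_up(rate, 1),
             stringsAsFactors = FALSE)
}

#' Neonatal mortality rate per 1000 live births
#'
#' Deaths within 28 days of life among live births, overall and optionally
#' by delivery year. Accepts either an `analysis_cohort` or explicit counts.
#'
#' @param cohort An `analysis_cohort`, or `NULL` when `deaths` and
#'   `live_births` counts are given directly.
#' @param stratify_by_year Also return one row per delivery year.
#' @param deaths,live_births Optional explicit numerator/denominator
#'   (scalars, or vectors with `strata` labels) overriding the cohort.
#' @param strata Stratum labels for explicit counts.
#' @return Data frame with one row per stratum: `deaths`, `live_births`,
#'   `rate_per_1000` (full precision) and `rate_printed` (1 dp, half-up).
#' @examples
#' neonatal_mortality_rate(deaths = 758, live_births = 30944)
#' @export
neonatal_mortality_rate <- function(cohort = NULL, stratify_by_year = FALSE,
                                    deaths = NULL, live_births = NULL,
                                    strata = "overall") {
  if (!is.null(deaths)) {
    stopifnot(length(deaths) == length(live_births))
    rows <- mapply(function(n, d, s) .rate_row(n, d, s), deaths, live_births,
                   strata, SIMPLIFY = FALSE)
    return(do.call(rbind, rows))
  }
  stopifnot(inherits(cohort, "analysis_cohort"))
  d <- cohort$data
  out <- .rate_row(sum(d$death_28d %in% TRUE), nrow(d), "overall")
  if (stratify_by_year) {
    for (yr in sort(unique(d$delivery_year))) {
      sub <- d[d$delivery_year == yr, , drop = FALSE]
      out <- rbind(out, .rate_row(sum(sub$death_28d %in% TRUE), nrow(sub),
                                  as.character(yr)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Cause-of-death distribution
#'
#' Per-cause counts and percentages of classified deaths, overall and
#' optionally stratified by year.
#'
#' @param causes Factor or character vector of assigned causes (from
#'   [classify_deaths()]), or a named count vector.
#' @param year Optional vector of delivery years parallel to `causes` for
#'   stratification.
#' @return Data frame with `stratum`, `cause`, `n`, `pct` (full precision)
#'   and `pct_printed` (1 dp half-up). Percentages within a stratum sum to
#'   100 before rounding.
#' @examples
#' cause_distribution(c(congenital_anomaly = 138, infection = 178,
#'                      prematurity = 209, asphyxia = 188, unknown = 37))
#' @export
cause_distribution <- function(causes, year = NULL) {
  if (is.numeric(causes) && !is.null(names(causes))) {
    counts <- causes
    lvls <- names(causes)
    strata <- list(overall = counts)
  } else {
    causes <- factor(as.character(causes), levels = cod_causes())
    lvls <- cod_causes()
    strata <- list(overall = table(causes))
    if (!is.null(year)) {
      for (yr in sort(unique(year))) {
        strata[[as.character(yr)]] <- table(causes[year == yr])
      }
    }
  }
  rows <- lapply(names(strata), function(s) {
    cnt <- as.numeric(strata[[s]])
    tot <- sum(cnt)
    pct <- if (tot > 0) 100 * cnt / tot else rep(NA_real_, length(cnt))
    data.frame(stratum = s, cause = lvls, n = cnt, pct = pct,
               pct_printed = round_half_up(pct, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorical variable by 28-day vital status
#'
#' Counts and within-status column percentages for a maternal or infant
#' categorical variable, using complete cases for that variable (so each
#' variable carries its own denominator, as registry tables print).
#'
#' @param cohort An `analysis_cohort`.
#' @param variable Name of a factor/logical column in the cohort data.
#' @return List with `table` (level, status, n, pct, pct_printed) and
#'   `denominators` (non-missing live births per status).
#' @export
categorical_table <- function(cohort, variable) {
  stopifnot(inherits(cohort, "analysis_cohort"))
  d <- cohort$data
  valid <- names(d)[vapply(d, function(x) is.factor(x) || is.logical(x), TRUE)]
  if (!variable %in% names(d)) {
    stop(sprintf("unknown variable '%s'; valid variables: %s", variable,
                 paste(sort(valid), collapse = ", ")), call. = FALSE)
  }
  v <- d[[variable]]
  if (is.logical(v)) v <- factor(v, levels = c(FALSE, TRUE),
                                 labels = c("no", "yes"))
  status <- factor(ifelse(d$death_28d %in% TRUE, "died", "alive"),
                   levels = c("died", "alive"))
  keep <- !is.na(v)
  tab <- table(level = v[keep], status = status[keep])
  den <- colSums(tab)
  rows <- expand.grid(level = rownames(tab), status = colnames(tab),
                      stringsAsFactors = FALSE)
  rows$n <- as.integer(tab[cbind(rows$level, rows$status)])
  rows$pct <- 100 * rows$n / den[rows$status]
  rows$pct_printed <- round_half_up(rows$pct, 1)
  list(variable = variable, table = rows,
       denominators = stats::setNames(as.integer(den), names(den)))
}
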