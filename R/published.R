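# Published aggregate counts from the Belagavi (Karnataka, India) MNHR site,
# 2014-2018: the enrollment cascade, 28-day mortality by year, the
# cause-of-death tally, and the exposure-by-outcome cells whose crude risk
# ratios the closed form reproduces. These are reporting-level inputs (no
# record-level data), used for worked examples and verification.

#' Published Belagavi registry aggregate counts, 2014-2018
#'
#' Aggregate counts from the Belagavi site of a population-based Maternal
#' Newborn Health Registry: the enrollment/exclusion cascade, live births
#' and 28-day deaths per year, cause-of-death tallies per year, delivery
#' location and attendant among deaths, birth-weight composition of deaths,
#' and the 2x2 exposure cells for preterm birth, multiple gestation and
#' parity.
#'
#' @return A nested list of named integer counts.
#' @examples
#' pc <- published_counts()
#' neonatal_mortality_rate(deaths = pc$deaths_by_year,
#'                         live_births = pc$live_births_by_year,
#'                         strata = names(pc$deaths_by_year))
#' @export
published_counts <- function() {
  years <- as.character(2014:2018)
  list(
    cascade = c(screened = 47614, non_resident = 8578,
                maternal_death_before_delivery = 11, miscarriage = 4929,
                medical_termination = 2542, stillbirth = 884,
                mothers_included = 30657, live_births = 30944,
                neonatal_deaths = 758, missing_cod_form = 8,
                cod_deaths = 750),
    live_births_by_year = stats::setNames(
      c(6789, 6623, 6219, 5774, 5539), years),
    deaths_by_year = stats::setNames(c(194, 167, 153, 151, 93), years),
    cod_deaths_by_year = stats::setNames(c(193, 167, 152, 149, 89), years),
    cause_counts = c(congenital_anomaly = 138, infection = 178,
                     prematurity = 209, asphyxia = 188, unknown = 37),
    cause_counts_by_year = list(
      `2014` = c(congenital_anomaly = 39, infection = 65, prematurity = 36,
                 asphyxia = 44, unknown = 9),
      `2015` = c(congenital_anomaly = 31, infection = 45, prematurity = 44,
                 asphyxia = 41, unknown = 6),
      `2016` = c(congenital_anomaly = 25, infection = 25, prematurity = 57,
                 asphyxia = 40, unknown = 5),
      `2017` = c(congenital_anomaly = 31, infection = 29, prematurity = 41,
                 asphyxia = 37, unknown = 11),
      `2018` = c(congenital_anomaly = 12, infection = 14, prematurity = 31,
                 asphyxia = 26, unknown = 6)),
    delivery_location_deaths = c(hospital = 568, clinic_health_center = 133,
                                 home = 39, other = 17),  # denominator 757
    birth_weight_deaths = c(`lt1000` = 108, `1000-1499` = 112,
                            `1500-2499` = 254, `2500plus` = 276),  # of 750
    # 2x2 cells (events among exposed, exposed total, events among
    # unexposed, unexposed total), death within 28 days as the event
    two_by_two = list(
      preterm = c(a = 364, n1 = 3235, c = 394, n0 = 27708),
      multiple = c(a = 75, n1 = 572, c = 683, n0 = 30371),
      parity_0 = c(a = 329, n1 = 11914, c = 360, n0 = 16921),
      parity_3plus = c(a = 69, n1 = 2106, c = 360, n0 = 16921))
  )
}
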