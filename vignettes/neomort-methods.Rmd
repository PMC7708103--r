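---
title: "Methods: neonatal mortality analysis for clustered perinatal registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal mortality analysis for clustered perinatal registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neomort)
```

## The problem

Population-based perinatal registries in low-resource settings — the
Maternal Newborn Health Registry (MNHR) design is the model here — enrol all
pregnant women residing in defined geographic study clusters (roughly
300–500 deliveries per cluster-year), follow each pregnancy to delivery and
each live-born infant to day 28, and administer a cause-of-death
questionnaire when an infant dies. Three analytical tasks follow: assign a
cause to each neonatal death with a reproducible algorithm rather than
clinician judgement; estimate neonatal mortality rates (NMR, deaths within
28 days per 1,000 live births) and the cause distribution; and quantify the
association of maternal and neonatal characteristics with 28-day death while
respecting the within-cluster correlation that the geographic design
induces. `neomort` implements this pipeline end to end, together with a
seeded synthetic registry generator so every stage is testable without
access to any confidential record-level data.

## Cohort construction

`build_cohort()` applies the standard exclusion cascade in a fixed order:
mothers not resident in a study cluster, mothers who died before delivery,
then pregnancy losses (miscarriage, medically terminated pregnancy,
stillbirth). Every exclusion is counted by reason, and the ledger plus the
retained live births always reconcile exactly with the input totals — an
invariant asserted on every generated dataset in the test suite. Each
live-born infant of a multiple gestation is a separate analysis row sharing
its mother's covariates, which is how registry tables count infants.
Whether a loss is a miscarriage or a stillbirth is an input label, not
recomputed from gestational age: the generator labels losses under 20
completed weeks miscarriage and at or over 20 weeks stillbirth, but real
data keep whatever the registry recorded. Missing covariates are retained in
the cohort and handled complete-case per analysis, which is why each
variable carries its own denominator downstream.

## The hierarchical cause-of-death algorithm

`assign_cause()` walks a fixed hierarchy and returns exactly one of five
causes plus a provenance code identifying the rule that fired:

1. a major congenital anomaly dominates everything;
2. otherwise any infection sign or suspicion (tetanus, omphalitis, sepsis,
   pneumonia, or suspected infection) gives **infection**;
3. otherwise a term infant (≥ 37 completed weeks) with breathing difficulty
   at birth or respiratory distress is **asphyxia**; a term infant with
   neither is **unknown**;
4. otherwise a moderately preterm infant (34 to < 37 weeks, or 2000 to
   < 2500 g when GA is missing) with breathing difficulty and/or any
   maternal pregnancy complication is **asphyxia**;
5. otherwise GA < 34 weeks and/or weight < 2000 g is **prematurity**;
6. a moderately preterm death with no implicating sign — a case the quoted
   rule set does not assign — is classified **prematurity**, on the view
   that it is a preterm death with nothing else implicated, and tagged with
   its own provenance code (`moderate_preterm_residual`) so users can audit
   exactly which assignments rest on this package decision.

Boundary conventions are explicit and config-visible via `cod_thresholds()`:
term means GA ≥ 37.0 completed weeks; the moderate band is `[34, 37)` weeks
or `[2000, 2500)` g; the early rule uses strict `< 34` weeks / `< 2000` g.
When GA and weight are both present and discordant, GA governs band
membership and the weight thresholds act only as a fallback for missing GA —
the weight bands read most naturally as a proxy for unknown gestational age.
"Present" and "suspected" infection are treated identically, and breathing
difficulty at birth and respiratory distress are kept as two input fields,
either of which satisfies the asphyxia sign criterion. A record with neither
GA nor weight cannot be banded and is returned as unknown with a warning
rather than an error, so one malformed record never aborts a batch. GA
plausibility filtering (e.g. a recorded GA of 55 weeks) is deliberately left
to the caller; the classifier takes its inputs at face value.

The test suite checks the classifier two ways: targeted examples for each
rule, and exhaustive factorial grids compared against an independently
written nested-if oracle with a different code structure.

## Rates, distributions, rounding

`neonatal_mortality_rate()` and `cause_distribution()` keep full-precision
values and add a printed representation rounded **half-up** to one decimal,
the convention of published epidemiological tables (R's own `round()` rounds
half to even and would print 24.45 as 24.4). Percentages within a stratum
sum to 100 exactly before rounding, and stratified numerators and
denominators must sum to the overall ones — both are asserted in tests.
`categorical_table()` uses per-variable complete-case denominators, matching
the varying denominators of registry tables.

## Relative risks under clustering

Risk ratios, not odds ratios, are the estimand throughout: the outcome is
common in some exposure strata (half of very-low-birth-weight infants die),
so a log-link binary-outcome model is used and exponentiated coefficients
are relative risks.

`crude_rr()` is the closed form on a 2×2 table with the standard log-scale
Wald interval, `exp(log RR ± 1.959964 · √(1/a − 1/n1 + 1/c − 1/n0))`. Zero
cells flag the estimate as unbounded rather than raising. The closed form
doubles as a verification surface: the published crude estimates that do not
depend on unpublished cluster assignments (preterm birth, multiple
gestation, parity) are reproduced from the printed count cells to two
decimals.

`cluster_rr()` and `continuous_rr()` fit marginal (population-averaged)
models by generalized estimating equations with robust (sandwich) variance
clustered on study cluster. The GEE machinery is implemented in the package
(Fisher scoring on the estimating equations, cluster-wise bread/meat
accumulation) because no GEE fitter is available in the dependency stack;
the independence case is cross-checked in the tests against a standard GLM
with a cluster-robust covariance, and in the singleton-cluster limit it must
match the ordinary maximum-likelihood fit to 1e−6 relative. The working
correlation defaults to independence — with a robust variance this is
consistent regardless of the true correlation, and it is the conventional
choice when the source analysis does not state a structure — with
exchangeable available via `corstr = "exchangeable"` (moment estimator for
the common intra-cluster correlation, analytic inverse of the exchangeable
working matrix).

Two numerical decisions matter in practice. First, log-binomial models
fail when a fitted risk reaches 1; the fitter detects this and falls back to
the Poisson (count) variance with the same log link — the modified-Poisson
risk model — tagging the result so the method column records which variance
was used. Second, convergence is declared on either a coefficient-change or
a quasi-likelihood-change criterion; the latter handles exposure levels
with zero events, where the level's coefficient drifts toward −∞ exactly as
a GLM at the boundary and the risk for that level tends to zero. Fits with
a single cluster are refused outright: the sandwich estimator is degenerate
there. The per-variable p-value is a joint multi-degree-of-freedom Wald test
across the exposure's non-reference levels (robust covariance), not the
minimum of the per-level p-values.

## The predictive model: QIC forward selection and marginal R²

`fit_multivariable()` fits the multivariable model with Poisson variance
from the start (the standard choice for a multivariable risk-ratio model,
where log-binomial convergence is fragile). `qic()` implements the
quasi-likelihood under the independence model criterion,

QIC = −2·QL(μ̂; independence) + 2·trace(Ω̂ V̂),

with QL the quasi-likelihood of the fitted means under the independence
working model, Ω̂ the model-based information under independence, and V̂ the
robust covariance. On independent, correctly specified data the penalty
approaches 2p and QIC approaches the classical information criterion — an
equivalence the tests assert within 2%. `forward_select()` is greedy: start
from the intercept, add the candidate that minimizes QIC, stop when no
addition lowers it, ties broken by candidate list order. Adding a pure-noise
covariate lowers QIC with probability roughly P(χ²₁ > 2) ≈ 0.16, so noise
occasionally enters any QIC-selected model; the test suite asserts the
penalty property at the rate this statistic actually has (QIC rises in at
least 75% of replicates, with a positive mean increase) rather than
pretending the criterion never admits noise.

`marginal_r2()` is the squared-error form 1 − Σ(y − μ̂)²/Σ(y − ȳ)² over all
analysis records: 0 for an intercept-only model, 1 for a saturated fit. For
a rare binary outcome this quantity is structurally modest — even a model
with strong risk factors leaves most Bernoulli variability unexplained — so
the package records its value on synthetic data as a regression snapshot
(band 0.02–0.25 under the default generator), not as a reproduction of any
published value, which would require the original record-level data.
Essential-newborn-care and treatment variables are excluded from the default
candidate set: their occurrence is a consequence of the infant's condition,
not an antecedent risk factor.

## The synthetic registry generator

`generate_registry()` draws, per cluster-year, a uniform 300–500 deliveries
(20 clusters over 2014–2018 by default — the cluster count is a
configuration choice, not a registry fact); maternal covariates
independently from registry-style marginals; an exclusion cascade with the
published cascade fractions; gestational age from a term/preterm mixture
(term component mean 38.8, sd 2.3 weeks; preterm component mean 33.5, sd
3.0; twin pregnancies draw the preterm component with elevated probability);
and birth weight conditional on GA (linear mean, 165 g per week around a
2900 g term mean, sd 420 g), tuned so the birth-weight band frequencies
approximate a real registry's composition. Death within 28 days follows a
log-link model: baseline risk 0.009 for the reference pattern with log-RR
effects on birth-weight band, antenatal-care visits, parity and education,
plus a cluster random effect (sd 0.2 on the log scale, truncated at ±2.5 sd
so no covariate pattern can realize a probability above 1 — the
configuration validator additionally rejects any effect combination whose
worst-case linear predictor is positive, naming the offending pattern). The
generating effect sizes are deliberately milder than the most extreme
published adjusted estimates (a relative risk of 80 for the smallest
infants cannot coexist with a log link, positive co-effects and valid
probabilities), which is also why the synthetic marginal R² sits below what
a real registry would show; the implied overall NMR lands near 24–25 per
1,000. Each death receives a latent cause drawn from the target cause
mixture restricted to the causes the classifier could actually return for
that record's GA and maternal-complication flag (a latent "unknown" must be
term, a latent "asphyxia" at least moderately preterm), and emits its
defining questionnaire sign with probability `sign_fidelity` (default 0.9);
at fidelity 1 the classifier recovers the latent labels exactly, a
round-trip the tests assert. ENC and treatment flags are drawn conditional
on vital status.

Random draws are split into per-phase streams (structure, covariates,
outcomes, deaths, signs) so extending one phase cannot perturb another
across package versions, and the whole registry is byte-identical under a
repeated seed. What the generator does **not** emulate, and therefore what
passing tests cannot show about real data: covariate dependence (ANC visits
and education are independent here, correlated in reality), the secular
decline in mortality over calendar years (a `year_log_rr` option exists but
defaults to off), informative missingness, geography beyond cluster labels,
and any ENC/treatment effect on survival (those flags are decorative
consequences of status, matching their excluded role in the models).

## Validation scale

The simulation-based checks run at desk scale: CI coverage of the
generating log-RR uses 200 replicates of ~5,000 pregnancies in 20 clusters
(coverage of the nominal 95% interval must be at least 90% for both the
crude and the clustered estimator); forward-selection recovery uses 100
replicates of ~4,000 pregnancies with one true predictor among four
candidates; the classifier/oracle comparison is exhaustive over a factorial
grid. `scripts/acceptance.R` re-runs all of these from scratch plus the
closed-form reproductions from the published aggregate counts.

## Known limitations

The published cluster-adjusted estimates and the published marginal R² of
the original analysis embed cluster assignments that were never released;
they are verified here only through the properties above (degenerate-cluster
equivalence, coverage, ordering of the adjusted birth-weight RRs), not
value-for-value. The exchangeable working correlation uses the standard
moment estimator without small-sample corrections. The sandwich variance is
asymptotic in the number of clusters; with 20 clusters the intervals are
mildly anti-conservative, visible as coverage a point or two below nominal
in the acceptance runs.
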