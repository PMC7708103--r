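Package: neomort
Title: Neonatal Mortality Analysis for Clustered Perinatal Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing neonatal mortality in prospective,
    population-based perinatal registries with geographically defined
    study clusters, modelled on the Maternal Newborn Health Registry
    (MNHR) design. Provides cohort construction with an auditable
    exclusion cascade, the hierarchical Global-Network-style cause of
    death classification algorithm (congenital anomaly, infection,
    asphyxia, prematurity, unknown), neonatal mortality rates and cause
    distributions, crude and cluster-adjusted relative risks via
    log-link marginal models with robust (sandwich) variance,
    QIC-based forward selection of a predictive model with marginal
    R-squared, and a seeded generator of synthetic clustered registry
    data for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
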