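Package: ricmodel
Title: Immuno-Competition Dynamics of Cancer-Infection Comorbidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a two-disease immuno-competition model in
    which a pre-cancerous clone and a chronic infection compete for a shared
    pool of naive T-cells. Provides the dimensional and dimensionless model
    equations, steady-state and stability analysis, separatrix and
    basin-of-attraction computation, saddle-node bifurcation scans over the
    naive T-cell production rate and its age proxy, virtual-patient subtype
    classification, on-off naive T-cell therapy simulation, and cohort
    statistics for clonal-hematopoiesis screening data, together with
    synthetic-data generators for screening cohorts and prevalence-by-age
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
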