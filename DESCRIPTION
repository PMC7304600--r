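Package: pmslt
Title: Proportional Multi-State Life Table Modelling for Obesity
    Prevention Policy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A cost-effectiveness modelling pipeline for population-level
    obesity prevention policies. Intervention effects expressed as kilojoule
    intake changes, MET-minutes of physical activity or BMI (z-score) shifts
    are translated into risk-factor changes, converted to potential impact
    fractions by the distribution-shift (BMI) and relative-risk-shift
    (physical activity) methods, and propagated through a proportional
    multi-state life table Markov cohort model with parallel disease
    sub-lifetables to obtain discounted health-adjusted life years and
    healthcare cost offsets. Includes intervention costing with wage
    on-costs and price indexing, ICER computation and dominance
    classification, cost-effectiveness league tables and portfolio
    summaries, qualitative implementation-considerations ranking,
    Monte Carlo parameter uncertainty, univariate sensitivity and
    threshold analyses, and a synthetic-epidemiology generator so that no
    external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
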