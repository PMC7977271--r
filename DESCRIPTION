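Package: riskstrat
Title: Evaluating Primary-Care Risk Stratification Against Condition-Category Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how well primary-care risk stratification
    identifies patients at high risk of future utilization. Computes
    hierarchical-condition-category (HCC) style risk scores from age, sex and
    diagnosis codes; converts continuous scores to size-matched risk tiers
    with tie-preserving quantile cut-points; quantifies concordance between
    practice-assigned and algorithmic high-risk flags (contingency tables,
    percent agreement, Cohen's kappa); and measures predictive performance
    against dichotomized emergency-department, hospitalization and
    expenditure outcomes, including paired comparisons of sensitivities
    (discordant-pair exact test) and positive predictive values (delta-method
    test on the log relative PPV). A calibrated synthetic-population
    generator emulates the demographic, diagnostic and utilization structure
    of a stratified primary-care panel so the full pipeline is testable
    without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
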