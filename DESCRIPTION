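Package: simogtt
Title: Mechanistic Modelling of the Oral Glucose Tolerance Test with Incretin Effect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and single-subject identification of a six-compartment
    glucose-insulin model of the oral glucose tolerance test (OGTT) in which
    gut glucose content drives incretin-augmented insulin secretion. Provides
    weighted least-squares estimation of log-parameters by multi-start
    Nelder-Mead with asymptotic covariance, empirical insulin
    sensitivity/secretion indices (HOMA, insulinogenic index, AUC ratios),
    log-normal synthetic OGTT cohort generation, visual predictive checks,
    residual diagnostics, and group comparison statistics (one-way ANOVA with
    LSD post-hoc tests under Hochberg correction, percentile trimming,
    correlation panels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
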