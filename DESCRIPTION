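Package: sympat
Title: Latent Class Analysis of Symptom Patterns and Health Service Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying symptom-pattern subgroups in survey
    cohorts and relating them to linked health-service use. Recodes
    four-level symptom frequency items into three-category indicators,
    fits polytomous latent class models by maximum likelihood (EM with
    multiple random starts, missing indicators handled under MAR),
    computes model-comparison and class-separation diagnostics (AIC/BIC
    on the G-squared and -2LL scales, relative entropy, average posterior
    probabilities, replicate stability), and estimates
    classification-error-corrected associations between latent classes,
    covariates and distal service-use outcomes via the
    Bolck-Croon-Hagenaars (BCH) weighting approach, with optional
    inverse-propensity balancing. A synthetic-cohort generator with a
    known latent-class truth supports parameter-recovery and calibration
    studies without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
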