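Package: hccmarkov
Title: Markov Cohort Decision Model Comparing Resection and Chemoembolization
    for Intermediate-Stage Liver Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-arm Markov cohort state-transition model comparing liver
    resection with transarterial chemoembolization for intermediate-stage
    hepatocellular carcinoma in cirrhotic patients, over a 15-year horizon
    with annual cycles and half-cycle correction. Includes the parameter
    estimation layer (declining exponential approximation of life expectancy
    conversions, Freeman-Tukey double-arcsine pooling with DerSimonian-Laird
    random effects, Wilson score intervals), deterministic one-way/two-way
    sensitivity analyses and tornado diagrams, second-order Monte Carlo
    probabilistic sensitivity analysis by microsimulation, and a synthetic
    patient-level validation cohort with propensity-score matching,
    Kaplan-Meier comparison and proportional-hazards analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
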