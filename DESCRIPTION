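Package: dualtraj
Title: Group-Based Single and Dual Trajectory Models for Longitudinal
    Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Latent class growth analysis for repeated binary outcomes in
    panel data: finite mixtures of logistic trajectories fitted by EM
    (group-based trajectory modeling), a dual-trajectory extension linking
    two outcome series through a joint group-membership matrix with
    conditional-probability summaries, BIC/AIC model selection over a grid
    of group counts, posterior classification diagnostics, baseline
    characteristic tables with chi-square tests, multinomial logistic
    regression of group membership on covariates, and a synthetic panel
    generator emulating an eight-wave health-panel cohort with declining
    follow-up participation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
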