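Package: twophasesim
Title: Two-Phase Sampling Designs for Biomarker Studies with Time-to-Event
    Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for planning two-phase
    (cohort subsampling) studies that measure a new binary biomarker on a
    subset of a survival cohort. Generates phase-I cohorts from a Weibull
    proportional-hazards model with a confounder, an independent risk
    factor and a surrogate of the biomarker; draws phase-II samples under
    simple random, probability-proportional-to-size, case-control
    (optionally stratified or post-stratified by auxiliary variables),
    nested case-control and counter-matching designs; computes design
    weights including Samuelsen-type inclusion probabilities for risk-set
    designs; fits an inverse-probability-weighted Cox model with a
    design-based variance; and summarises replications into bias,
    empirical standard error, mean square error, design effect, coverage
    and power, including power curves over the phase-II sample size.
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
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
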