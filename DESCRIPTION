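Package: popimpact
Title: Population Impact of Clinical Interventions from Trial Effectiveness and Uptake
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the population impact of clinical interventions as the
    product of trial effectiveness and clinician uptake. Effectiveness is
    summarised as a pooled relative risk from random-effects (DerSimonian-Laird
    or REML) meta-analysis of two-arm trials; uptake is estimated from the
    recruitment cascades of pragmatic randomised trials (practices approached,
    clinicians participating), with exact and asymptotic binomial confidence
    intervals for single trials and a random-intercept binomial logistic model,
    fitted by adaptive Gauss-Hermite quadrature, for pooling uptake across
    trials. Includes Monte Carlo propagation of uncertainty to the impact
    scale, an encounter-level decomposition (intervention used and effective /
    used but ineffective / not taken up), intervention ranking, summary-table
    and decomposition reporting, and a synthetic-data generator with the same
    generative structure for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    metafor,
    lme4,
    withr
Config/testthat/edition: 3
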