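Package: sulfurflux
Title: Community Flux Balance Modelling and Longitudinal Metabolome
    Statistics for Gut Microbial Sulfur Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying host-microbial sulfur co-metabolism at desk
    scale. Builds abundance-weighted, diet-constrained gut microbial community
    models from strain-level reconstructions and computes per-metabolite net
    maximal secretion potentials by flux balance analysis; provides seeded
    generators for toy strain panels, longitudinal case-control metabolome
    cohorts, and incident-disease survival cohorts; and implements the
    accompanying statistics: fractional (logit) regressions with bootstrap
    standard errors, mixed-model trajectory typing and pairwise
    metabolite-group interaction screens, medication change-on-change models,
    per-standard-deviation Cox incidence analysis with fixed-effect
    meta-analysis, and a greedy recursive-elimination case-control matcher.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    lme4,
    survival,
    MASS,
    pROC,
    sandwich,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    metafor,
    withr
Config/testthat/edition: 3
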