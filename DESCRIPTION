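Package: ebmseq
Title: Event-Based Modelling of Regional Brain Atrophy Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the most likely sequence in which brain regions become
    atrophic from cross-sectional and short longitudinal cohorts of regional
    volumes, using an event-based model: nuisance-covariate adjustment and
    region selection, fixed-component Gaussian mixture models of normal and
    abnormal volume, greedy-ascent search and Metropolis MCMC over event
    orderings, maximum-likelihood staging of individual scans, cross-validated
    positional variance diagrams, and downstream mixed-effects associations
    between model stage and clinical variables. Includes a synthetic cohort
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
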