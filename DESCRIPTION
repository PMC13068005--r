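Package: delaytwin
Title: Stochastic Delay Differential Equation Digital Twins of
    Inflammatory Biomarker Cascades
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates virtual patient cohorts whose inflammatory
    biomarker dynamics (neutrophils, C-reactive protein, albumin and a
    latent cardio-inflammatory output) follow stochastic delay
    differential equations integrated with a delay-aware Euler-Maruyama
    scheme.  Provides event labelling by prevalence-calibrated threshold
    exceedance, sensitivity analyses (event prevalence variation, outcome
    noise at the event-definition stage, inter-individual parameter
    heterogeneity), rank-based discrimination and survival statistics on
    simulated cohorts, and cross-sectional delay-proxy ratios
    (CRP/(neutrophils+1) and CRP/albumin) for tabular biomarker data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    survival,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
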