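Package: emoconn
Title: Effective Connectivity of Emotional Face Processing via DCM and PPI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference pipeline for a four-region (V1, fusiform
    gyrus, amygdala, orbitofrontal cortex) dynamic causal model of emotional
    face processing. Provides a bilinear neural state equation coupled to a
    balloon-windkessel hemodynamic observation model, variational-Laplace
    model inversion with free-energy model evidence, staged Bayesian model
    selection over a 21-model / 7-family space of emotion-modulated
    connections, region-of-interest time-series extraction with eigenvariate
    summaries and subject inclusion rules, psychophysiological-interaction
    (PPI) regression with group comparison and symptom correlation, and a
    two-cohort synthetic BOLD generator whose ground truth encodes a
    group-by-valence reversal of modulatory connectivity.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    RNifti,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
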