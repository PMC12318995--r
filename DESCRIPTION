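Package: dstp
Title: Dual-Stage Two-Phase Diffusion Modelling of Conflict Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trial-level simulation and simulation-based estimation of the
    dual-stage two-phase (DSTP) model of selective attention for Stroop-type
    conflict tasks. Provides a fast Euler-Maruyama simulator for the two
    racing diffusion stages, closed-form two-boundary Wiener oracles for
    validation, a multi-start Nelder-Mead fitting routine that minimises a
    likelihood-ratio chi-square (G2) statistic over reaction-time quantile
    bins, a synthetic Shape Stroop session and cohort generator with known
    generating parameters, and the group-level inferential layer used in
    ageing studies of selective attention: interquartile-range outlier
    fences, Greenhouse-Geisser corrected mixed ANOVA with partial eta
    squared, and Tukey-corrected pairwise comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
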