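Package: dfcstates
Title: Dynamic Functional Connectivity State Analysis for Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity (dFC) analysis of
    region-of-interest fMRI time series: windowed Fisher-z correlation features,
    empirical-Bayes multisite (ComBat) harmonization, exemplar-seeded two-stage
    k-means clustering into recurring connectivity states, per-subject temporal
    metrics (fractional occupancy, mean dwell time, state transitions), and a
    case-control statistical battery (Welch t with Satterthwaite degrees of
    freedom, Benjamini-Hochberg false discovery rate, Hedges g, chi-square,
    Greenhouse-Geisser corrected repeated-measures ANOVA, covariate-adjusted
    linear models, and clinical stratification). Includes a Markov-switching
    multivariate cohort simulator with planted connectivity regimes, group
    dynamics, and site effects so the whole pipeline is testable end to end
    without access to consortium imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    sva
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
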