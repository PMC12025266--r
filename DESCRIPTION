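Package: pocenmr
Title: Isotopic Enrichment Analysis for Proton-Observed Carbon-Edited NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies position-specific 13C isotopic enrichment of brain
    metabolites from paired reference/edited 1D proton spectra acquired with a
    POCE (proton-observed carbon-edited) pulse scheme. Provides a closed-form
    Lorentzian spectrum simulator with Gaussian-copula cohort generation and
    known ground truth, zero-order phase correction, asymmetric-least-squares
    baseline correction, TMSP chemical-shift calibration, fixed-window
    trapezoidal integration over curated chemical-shift ranges, enrichment
    ratios with internal-standard normalization, Spearman correlation networks
    with Benjamini-Hochberg false-discovery control and hub scoring, group
    summaries (percent depletion with bootstrap intervals, Lilliefors
    normality screening, one-way ANOVA with Tukey post hoc), and small
    utilities for behavioral and electrocorticography endpoints (discrimination
    index, turn ratios, censored beam-traversal times, Welch band power,
    JC-1 membrane-potential index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
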