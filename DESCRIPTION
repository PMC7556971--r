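Package: fruqcea
Title: Markov Cohort Cost-Effectiveness Model of Fruquintinib for
    Third-Line Metastatic Colorectal Cancer
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Cohort-level health-economic decision model comparing
    fruquintinib with best supportive care (BSC) as third-line treatment
    for metastatic colorectal cancer from the Chinese healthcare payer's
    perspective. Implements Weibull overall-survival extrapolation from
    trial medians or Kaplan-Meier coordinates, a three-state 4-week-cycle
    Markov cohort engine with exponential treatment discontinuation,
    discounted cost and QALY accumulation with one-off adverse-event
    burdens, deterministic calibration of the survival shapes to the
    published base case, one-way (tornado) and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and a
    pre/post price-negotiation scenario switch.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    flexsurv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
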