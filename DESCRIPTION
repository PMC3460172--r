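Package: serodx
Title: Multi-Marker Autoantibody Panel Design and Diagnostic Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating multi-marker serological
    diagnostic panels such as the seven-autoantibody EarlyCDT-Lung test.
    Implements panel positivity calling from titration-series dose-response
    checks and per-antigen cutoffs, Monte-Carlo direct search optimization of
    cutoff sets under a fixed-specificity or fixed-sensitivity constraint,
    occult-cancer-adjusted specificity via an individual lung-cancer risk
    model, exact binomial (Clopper-Pearson) confidence intervals,
    prevalence-based positive predictive value and accuracy, panel-version
    comparison statistics, and a seeded synthetic serology cohort generator
    for end-to-end validation without patient sera.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
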