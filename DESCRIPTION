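Package: cardioscreen
Title: Kinase-Inhibitor Cardiotoxicity Screening with Calcium-Transient
    Analysis and Levenberg-Marquardt Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for monolayer
    cardiotoxicity screens of kinase inhibitors on human iPSC-derived
    cardiomyocytes.  Generates synthetic 384-well screens with planted
    ground truth (plate maps, calcium-flux traces, cell counts, engineered
    tissue force traces); extracts calcium-transient peak magnitude and
    beat frequency with a control-derived noise floor, and contractility
    metrics (active tension, beat duration, contraction and relaxation
    slopes) from force traces; normalizes endpoints against blank wells,
    codes effects into signed standard-deviation bands, and provides
    one-way ANOVA with Fisher LSD comparisons; trains multilayer
    perceptrons with a from-scratch Levenberg-Marquardt optimizer,
    including 90/10 splitting, RMSE and R-squared evaluation and
    exhaustive architecture search; and ranks compounds by mean predicted
    normalized calcium peak magnitude over a constrained design grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
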