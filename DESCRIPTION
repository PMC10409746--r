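Package: ommdropout
Title: Dropout-Community Analysis for Synthetic Gut Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-species dropout experiments in defined
    (synthetic) gut bacterial communities such as the twelve-member Oligo-Mouse-
    Microbiota. Converts strain-specific qPCR readouts into detection-limit-censored
    absolute abundances, quantifies pairwise strain relationships through the r_abs
    ratio with exclusion / positive-dependency logic, scores per-environment keystone
    impact, tests community structure by Bray-Curtis ordination with confidence
    ellipses and PERMANOVA, calls metabolite consumption and production from feature
    tables, and summarises host readouts (histopathology score, cecal weight ratio).
    A generalized Lotka-Volterra serial-dilution simulator with bacteriocin and
    polysaccharide-acidification mechanism plugins provides ground-truth data for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
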