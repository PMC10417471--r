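Package: ovistereo
Title: Stereological Assessment of Ovarian Maturity in Fish
Version: 0.1.0
Authors@R:
    person("Ovistereo", "Developers", email = "ovistereo@example.org",
           role = c("aut", "cre"))
Description: Quantitative histology toolkit for assessing female maturity in
    teleost fish from ovarian cross-sections. Implements Glagolev point-count
    stereology on whole-section images (threshold segmentation, systematic
    uniform random grids of 500-600 points, per-structure germ-cell surface
    percentages), rule-based maturity staging on the ICES A-D scale from the
    most advanced oocyte stage present, gonadosomatic index and
    nuclear/cytoplasmic ratio computations, and maturity-ogive estimation
    (logistic L50 with non-parametric bootstrap confidence intervals and
    Nagelkerke R-squared). A synthetic-data module generates labelled ovary
    sections with exact ground-truth area fractions and fish populations with
    known maturity-by-length structure, so every stage of the pipeline is
    testable without histological slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
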