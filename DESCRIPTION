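Package: anthroval
Title: Reliability and Validity of Skinfold-Based Body-Composition Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how well skinfold-based anthropometric
    prediction equations agree with a criterion (DXA-style) measure of fat
    mass and lean mass in athletic cohorts. Implements five published
    fat-mass prediction equations (Durnin & Womersley; Slaughter; Withers;
    Wilmore & Behnke; Oliver), the Mirwald maturity-offset estimate with
    post-peak-height-velocity grouping, and the reliability and validity
    statistics used in method-comparison studies: technical error of
    measurement, typical-error coefficient of variation, two-way
    absolute-agreement intraclass correlation from variance components,
    Bland-Altman limits of agreement, Cohen's d effect sizes,
    normality-gated paired location tests and an acceptability verdict.
    A synthetic-cohort generator with known ground truth makes the whole
    pipeline testable end to end without access to athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    readr,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
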