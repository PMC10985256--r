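Package: actiwear
Title: Free-Living Actigraphy Processing and Cohort Statistics for Ataxia Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes epoch-level triaxial accelerometer counts from
    free-living wear protocols into digital activity measures, and runs the
    cohort-level statistics used to evaluate such measures as clinical-trial
    outcomes. Implements Choi-style non-wear detection with diary
    reconciliation and valid-wear-day selection; cut-point intensity
    classification, MET rate, moderate-to-vigorous activity bouts, triaxial
    vector magnitude and step rate; group comparison with a normality gate,
    Spearman correlation against clinical severity scales, paired
    longitudinal tests, odd/even-day test-retest reliability (ICC, SEM,
    minimal detectable change), standardized response means and two-arm
    trial sample sizes. A calibrated synthetic-cohort generator produces
    two-visit, two-placement recordings for a patient group and a control
    group so the full pipeline is testable without access to participant
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
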