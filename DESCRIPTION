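Package: hrconcord
Title: Agreement Analysis for Wearable Heart-Rate Validation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating optical wrist-worn heart-rate trackers
    against a criterion chest-strap monitor. Reduces multi-rate
    time-stamped heart-rate streams to a canonical 10-second epoch grid,
    time-matches nonzero tracker readings to the criterion, and computes
    method-comparison statistics: intraclass correlation with absolute
    agreement (ICC(2,1)), mean absolute error, mean absolute percentage
    error, Bland-Altman limits of agreement, criterion-ranked decile
    comparisons, and sensitivity/specificity of moderate-to-vigorous
    physical activity classification at 64% of age-predicted maximum
    heart rate. Includes a synthetic-data generator that emulates a
    laboratory cycling protocol and a free-living wear day with a
    phenomenological tracker-error model, so the full pipeline is
    testable without proprietary device exports.
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
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
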