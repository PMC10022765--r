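Package: rqit
Title: Research Question Importance Scoring and Best-Worst Scaling Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-attribute scoring of clinical research questions on a
    0-1000 interval scale with standard-error propagation, together with the
    statistical machinery used to build and validate such instruments:
    best-worst scaling choice-task designs, a Thurstone paired-comparison
    probit estimator of element utilities (common or respondent-specific
    dispersions, sum-to-zero identification), chance-corrected agreement
    statistics (two-way random-effects ICC, Gwet's AC2, modal percent
    agreement, committee-resampled ICC), RAND/UCLA Delphi disagreement
    analytics, and bibliometric validity analyses (Cramer's V, tertile
    logistic regression, log-citation regression). Includes simulators for
    Thurstonian best-worst responses, rating matrices with controlled
    agreement, and article records with controlled score-outcome
    associations. Ships the ANZMUSC Research Question Importance Tool
    (ANZMUSC-RQIT) utility table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
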