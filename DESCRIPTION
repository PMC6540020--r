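Package: biafit
Title: Settling-Value Calibration and Body-Fat Estimation for Dry-Electrode Bioimpedance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for wearable dry-electrode bioelectrical impedance analysis
    (BIA): feasibility screening of short timed impedance series, extrapolation
    of the settled contact impedance from the initial first-order transient via
    delta-ratio log-linear regression, anthropometric feature construction,
    percent-body-fat estimation by linear regression and small feed-forward
    neural networks, evaluation metrics (Pearson r, r-squared, standard error
    of estimate), and a seeded synthetic cohort generator emulating athlete
    anthropometrics and upper-body impedance measurements so the full pipeline
    can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
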