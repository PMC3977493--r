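Package: rygbtraj
Title: Percentile Weight-Loss Trajectories after Roux-en-Y Gastric Bypass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-centred prediction and tracking of body-mass-index
    trajectories during the first 36 months after Roux-en-Y gastric bypass
    (RYGB). Implements the published centred quantile-regression trajectory
    model (25th/50th/75th percentile BMI as cubic functions of months since
    surgery, with baseline-BMI and age main effects and time interactions),
    an exact simplex solver for fitting the same model to new cohorts by
    check-loss minimisation, anthropometric outcome extraction (percent
    excess weight loss, 6-month loss, weight-loss nadir) and percentile-band
    tracking of individual patients, a calibrated synthetic-cohort simulator
    with realistic visit schedules and follow-up attrition, cohort CSV
    readers with implausible-measurement cleaning, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
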