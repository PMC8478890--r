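Package: walkrisk
Title: Health-Risk Thresholds and Logit Modelling for PM2.5 Exposure on Walking Trips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the health risk of walking trips under fine
    particulate (PM2.5) exposure from personal monitoring data.  Heart-rate
    series are aggregated into fixed intervals and expressed as the
    heart-rate change rate (HR%) relative to a resting baseline;
    per-volunteer ROC curves against subjective safe/risk labels yield
    Youden-optimal HR% thresholds, which are mapped back to PM2.5
    concentrations; a five-covariate binary logit model (PM2.5, gender, age
    group, BMI band, HR%) is fitted by Newton-Raphson maximum likelihood to
    produce odds ratios, Wald tests and group risk curves.  A
    synthetic-cohort simulator reproduces the statistical structure such
    field campaigns assume, so the whole pipeline runs and is testable
    without access to volunteer data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
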