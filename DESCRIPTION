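Package: nvhap
Title: Electronic Surveillance and Pre/Post Evaluation of Non-Ventilator
    Hospital-Acquired Pneumonia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Surveillance and quasi-experimental evaluation toolkit for
    non-ventilator-associated hospital-acquired pneumonia (NV-HAP) in
    multi-site hospital systems. Implements a deterministic electronic
    surveillance definition over patient-day vital-sign, laboratory,
    imaging and antibiotic data; an ICD-10 discharge-coding definition
    with present-on-admission logic; temporal trend models (logistic,
    GEE definition comparison with cluster-robust errors, hurdle
    negative-binomial length-of-stay); and a counterfactual pre/post
    risk-difference estimator that standardizes over length of stay by
    the law of total probability, with delta-method covariance of
    site-specific estimates and correlation-aware inverse-variance
    pooling. Includes a synthetic multi-site cohort generator with
    known ground-truth intervention effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    sandwich,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
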