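Package: vertispend
Title: Spending and Quality Comparisons for Hospital-Owned Versus
    Physician-Owned Practices from Insurance Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A claims-analytics pipeline for measuring how vertical
    integration of physician practices into hospitals relates to annual
    patient spending and care quality. Provides patient attribution to
    physician organizations by plurality of primary-care visits over a
    24-month window, spending decomposition by Berenson-Eggers Type of
    Service (BETOS) category and site of care, median-price
    standardization to separate price from utilization effects,
    claims-based quality measures (30-day readmission, diabetes testing,
    screening mammography), and log-link quasi-likelihood, linear, and
    logistic models with standard errors clustered by physician
    organization. A synthetic claims generator with known ground-truth
    ownership effects makes every stage testable without proprietary
    insurer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
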