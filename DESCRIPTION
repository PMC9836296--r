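Package: cpgmediate
Title: Candidate-Gene CpG Methylation Mediation and Moderation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for candidate-gene DNA-methylation
    analyses of the maltreatment-depression association: CpG-unit quality
    control (missingness and zero-inflation filters, perfect-duplicate
    collapse, correlation/distance region grouping), score winsorization,
    per-CpG linear screening with data-driven confounder selection and
    Benjamini-Hochberg false-discovery-rate correction, screening-gated
    quasi-Bayesian Monte-Carlo causal mediation (ACME, proportion mediated,
    percentile confidence intervals), exposure-by-methylation moderation with
    mean-centering and simple slopes, and two cumulative methylation indices
    (a signed sum of mediating units and a tertile-coded methylation risk
    score). Includes a synthetic-cohort generator with planted mediation and
    moderation structure for parameter-recovery and error-calibration
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
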