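Package: langbias
Title: Meta-Epidemiological Estimation of Language Bias in Systematic Reviews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage meta-epidemiological analysis of language bias: within
    each meta-analysis a random-effects meta-regression estimates the
    difference in standardized mean difference (dSMD) between non-English and
    English trials, and the per-meta-analysis estimates are pooled across
    meta-analyses under random- and fixed-effect models. Includes Hedges' g
    effect sizes, DerSimonian-Laird and REML heterogeneity estimation, Firth
    bias-reduced logistic regression with profile penalized-likelihood
    confidence intervals for associating review characteristics with the
    inclusion of non-English studies, descriptive summaries of systematic-
    review characteristics, and synthetic-data generators emulating the
    nested trial structure and the review-characteristics table.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
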