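Package: gstcml
Title: Case-Control Association and Additive Interaction Analysis of GST
    Polymorphisms in Chronic Myeloid Leukemia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control association analysis of glutathione
    S-transferase (GSTM1/GSTT1 deletion, GSTP1 Ile105Val) genotypes,
    smoking, chronic myeloid leukemia risk and treatment response: odds
    ratios with Woolf confidence intervals under recessive, dominant and
    additive genetic models, Hardy-Weinberg goodness-of-fit testing,
    additive-scale gene-gene and gene-environment interaction measures
    (RERI, attributable proportion, synergy index) with an explicit
    convention for inestimable strata, Kaplan-Meier and log-rank response
    endpoints, and a synthetic cohort generator that reconstructs published
    marginal tables exactly or simulates cohorts under configurable
    genotype frequencies and odds-ratio effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
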