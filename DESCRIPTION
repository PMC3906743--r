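Package: coexreg
Title: Co-Expression Network Regulator Prioritisation for Transfection
    Microarray Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for small transfection
    microarray experiments aimed at validating predicted transcriptional
    regulators. Implements detection-filtered log2 normalization with
    within-chip standardization, per-contrast differential expression and
    Phenotypic Impact Factor (PIF) scoring, two-component Gaussian mixture
    modelling with tail-area FDR calling, PCIT co-expression network
    inference, module-to-regulator ranking, Regulatory Impact Factor
    (RIF) scoring across two-condition contrasts, fixed-effects ANOVA and
    delta-delta-Ct analysis of qPCR Ct tables, and hypergeometric
    gene-set enrichment. A synthetic-data module generates every input
    the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
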