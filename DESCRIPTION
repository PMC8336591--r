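Package: internof1
Title: Differentially Responsive Gene Sets Between Very Small Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects gene sets that respond differently between two very small
    cohorts of subjects, where each subject contributes one paired two-condition
    transcriptome (e.g. tumour versus matched normal). A single-subject stage
    fits a two-component Gaussian mixture to absolute log2 fold changes to call
    per-subject differentially expressed genes, scores each gene set with a
    two-sided Fisher exact test and a continuity-corrected log odds ratio, and
    a cross-cohort stage contrasts cohort means of those log odds ratios with
    an approximately standard-normal W statistic, Benjamini-Hochberg adjustment
    and a negative-means suppression rule. Also provides a moderated-GLM
    comparator on subject-level within-pair log ratios, a six-parameter
    simulator of paired tumour-normal cohorts with ground-truth enrichment
    labels, and a precision/recall benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    limma,
    edgeR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
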