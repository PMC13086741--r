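Package: valenceDE
Title: Negative-Binomial Differential Expression with Permutation-Based
    Empirical FDR and Valence Gene Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-tissue differential-expression analysis for three-treatment
    (naive, positive, negative social training) bulk RNA-seq designs:
    low-count filtering, median-of-ratios normalization, negative-binomial
    GLM Wald contrasts with heavy-tailed posterior-mode log-fold-change
    shrinkage, a per-gene empirical false-discovery procedure built from
    label-permuted refits, and rule-based classification of differentially
    expressed genes into context-unique, shared valence-independent
    (learning) and antagonistic valence-associated sets. Includes a
    negative-binomial count simulator that plants each gene class with
    known ground truth, so every stage of the pipeline is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
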