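Package: TumorSpecScreen
Title: Two-Step Screening of Tumor-Specific Expression Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a two-step strategy for discovering tumor-specific
    gene signatures from bulk expression data: differential expression of
    tumor versus matched normal tissue (fold-change, t-test and presence
    filters), followed by screening of the modulated genes against a
    multi-tissue panel of normal samples and rule-based classification into
    liver-specific, tumor-associated and tumor-specific signatures.
    Includes etiology-stratified runs with cross-setting overlap analysis,
    validation of a signature on an independent paired tumor/normal count
    cohort (full-quantile normalization, paired differential test with
    Benjamini-Hochberg FDR, direction-aware confirmation and cross-platform
    fold-change concordance), and a synthetic-cohort generator with planted
    signature-class genes so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, Microarray, RNASeq,
    Transcriptomics, Classification
RoxygenNote: 7.3.3
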