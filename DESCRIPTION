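Package: popmarkers
Title: Comparing FACS-Sorted Cell Population Transcriptomes and Discovering
    Marker Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for bulk RNA-seq comparison of FACS-sorted
    immune cell populations profiled from the same donors. Provides readers for
    featureCounts-style count matrices, sample sheets and GMT gene sets; TPM and
    median-of-ratios normalization; patient (batch) adjustment on the log scale;
    a simplified negative-binomial Wald test for differential expression with
    Benjamini-Hochberg correction; a percentile-rank transcriptome similarity
    statistic; two-step marker-gene discovery by differential expression and
    quantile non-overlap with specificity ranking; marker-panel based
    contamination QC; hypergeometric over-representation analysis; and a
    negative-binomial count simulator with planted population-specific genes,
    patient batch shifts and contamination mixtures for validation with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
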