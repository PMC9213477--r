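Package: relaccs
Title: Chromatin-Accessibility-Aware Targeted Panel Design for Liquid Biopsy
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating chromatin accessibility states into the
    design of targeted sequencing panels for cell-free DNA (cfDNA) liquid
    biopsy. Builds a consensus blood accessibility reference from ATAC-seq
    peak calls (fixed-width summit extension, blacklist filtering,
    score-per-million normalization, iterative non-overlapping peak
    consolidation, cell-type reproducibility filtering), computes the
    Relative Accessibility Score (RelAccS; log2 ratio of mean tumor to
    weighted blood normalized ATAC-seq counts), designs cancer-specifically
    accessible and inaccessible panels via RelAccS and blood-overlap
    filtering, negative-binomial differential accessibility testing, and
    cross-validated random-forest / linear-SVM / LASSO consensus feature
    selection, ranks mutation and differentially-methylated-region markers
    by RelAccS, and validates panels against cfDNA fragmentation patterns
    (depth, median fragment length, smoothed accessibility correlations)
    and tumor-cfDNA allele-frequency concordance. Includes seeded synthetic
    data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    glmnet,
    jsonlite,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
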