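Package: codoncontrib
Title: Sequence-Feature Drivers of Rapid Protein-Abundance Change Under
    Heat Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies how far codon usage, amino-acid composition,
    base/GC content, region lengths and transcriptional change explain
    short-term heat-stress protein fold changes.  Extracts CDS and UTR
    sequences from a genome plus GFF3 annotation, builds a per-gene
    sequence-feature matrix, derives transcript and protein fold changes
    from replicate abundance tables (with TMT-style missing-value
    imputation), screens features by correlation, decomposes explained
    variance with multivariate adaptive regression splines (forward hinge
    selection and GCV-based backward pruning) verified by ordinary least
    squares and elastic net, compares codon-frequency distributions
    across protein groups with tie-corrected Kruskal-Wallis tests, and
    performs hypergeometric term enrichment with Benjamini-Hochberg
    correction.  A synthetic-data generator with planted effects makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    glmnet,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
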