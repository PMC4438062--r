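Package: metastab
Title: Passage-Instability Analysis and Metastasis-Relevant Gene Calling
    for Cultured Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies gene-expression and copy-number instability of
    cultured cell lines across serial passages and calls passage-robust
    ("metastasis-relevant") genes from parental/metastatic cell-line pairs
    profiled at early and late passage.  Implements two-group differential
    expression with fold and significance thresholds and Benjamini-Hochberg
    FDR, per-doubling normalisation of regulated-gene counts, overlap
    enrichment of common regulated genes under an independence expectation,
    EASE-score (modified one-sided Fisher) positional clustering on
    chromosomes and cytobands, copy-number segment filtering and
    macro-aberration calling, copy-number/expression coincidence statistics
    with permutation support, and a four-way passage-combination
    consistency filter with pathway gene-set evaluation.  A synthetic-data
    generator with full ground-truth bookkeeping emulates the study design
    (parental/metastatic cell-line systems, early/late passage,
    triplicates) for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
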