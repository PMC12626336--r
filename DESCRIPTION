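Package: tempomics
Title: Integrative Time-Course Transcriptomic and Chromatin Accessibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of bulk RNA-seq and ATAC-seq time
    courses such as postnatal tissue growth series. Provides nested
    negative-binomial GLM likelihood-ratio testing of temporal differential
    expression with a sample-quality (RIN) blocking covariate, stringent
    fixed-width consensus peak construction from replicated peak calls,
    differential accessibility testing, PAM-based co-expression module
    discovery over Pearson distances, peak-gene correlation integration for
    putative enhancer inference, PWM motif scanning with hypergeometric
    enrichment, gene-set over-representation analysis, and delta-delta-Ct
    qPCR statistics. A synthetic-data generator with planted temporal
    modules, peak-gene links and motif instances makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
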