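Package: foxsplice
Title: DEG Filtering, MS Gene-Set Enrichment and Polypyrimidine-Tract
    Analysis for Helicase-Sensitive Intron Retention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for studying how depletion of a splicing
    helicase reshapes the CD4+ T cell transcriptome. Implements
    expression/fold-change filtering of gene-level RNA-seq summary tables,
    direction-of-effect (odds ratio x eQTL effect size) classification of
    multiple sclerosis susceptibility genes into pathogenic and protective
    sets, a seeded resampling test for DEG/gene-set overlap with an exact
    hypergeometric oracle, strand-aware extraction of splice-site windows
    and polypyrimidine tracts from genome FASTA plus BED intervals,
    position-frequency/sequence-logo mathematics, a log-odds splice-site
    strength score, and rank-based comparisons of site strength and
    py-tract base composition between retained and unaffected introns.
    A synthetic-data module generates every input with the statistical
    structure the analysis assumes, so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
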