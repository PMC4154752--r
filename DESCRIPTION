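Package: repeatproof
Title: Assembly Evaluation for Genes and Transposable Elements with
    Synthetic Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a draft genome assembly resolves genes and
    transposable elements (TEs) relative to a trusted reference. Provides
    best-placement filtering of contig-to-reference alignments, assembly
    contiguity and correctness metrics (N50/NG50/NA50 families, per-100-kbp
    error rates, misassembly detection, end-overlap supercontig merging),
    per-feature containment and identity assessment by local alignment,
    read error profiling with a heterozygosity-corrected per-base error
    estimator, coverage-gap analysis with a pseudo-assembly simulation,
    a random-intercept logistic model of TE assembly success, and coverage
    down-sampling experiments. A synthetic-data generator plants TE
    families, genes, long reads, and draft contigs with known truth labels
    so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    lme4,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
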