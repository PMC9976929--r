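Package: ciscall
Title: Common Insertion Site Detection for Transposon Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-step analysis of Sleeping Beauty and PiggyBac insertional
    mutagenesis screens. A random-forest mutagenesis model learns neutral
    transposon insertion rates at TA/TTAA motif sites from local sequence
    context and distances to genomic and epigenomic features (TSS, TTS, gene
    bodies, DNase- and ATAC-seq peaks), converting calibrated classifier odds
    into per-site Poisson rates. A selection model then regresses per-sample,
    per-region insertion counts against the aggregated neutral rates with
    sequencing-depth and chromosome factors, tests each region's selection
    coefficient with a one-sided Wald test, and controls the family-wise
    error rate by Bonferroni correction. Includes a fully synthetic screen
    simulator, diagnostics (sequence logos, fold-enrichment profiles,
    precision curves, Jaccard agreement), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ranger,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
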