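Package: enhSelScan
Title: Selection Scans on Embryonic Enhancers Against Local Neutral References
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether tissue-specific embryonic enhancers evolve
    rapidly because of natural selection rather than elevated mutation.
    Enhancer substitution distances (D) between mouse and a close relative are
    estimated by maximum likelihood under a GTR model with discrete-gamma rate
    heterogeneity and normalized by local neutral references: fourfold
    degenerate sites (d4) and non-first-intron intron sites (di) of the
    nearest orthologous gene. Each enhancer is classified as positively
    selected, purifying or neutral with Fisher's exact test on substituted
    versus unsubstituted sites; GC-biased gene conversion is diagnosed by
    polarizing mouse-lineage substitutions at ancestrally A/T sites with a
    rat/human outgroup rule; and covariate-controlled comparisons (pleiotropy,
    gene essentiality, expression bins) are provided. A fully parameterized
    sequence-evolution simulator with known per-enhancer selection classes and
    optional GC-fixation bias supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, Genetics, Epigenetics, SequenceMatching, Phylogenetics
RoxygenNote: 7.3.3
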