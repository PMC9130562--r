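Package: mosaicscan
Title: Genome Mosaicism Scans and Candidate-Gene Outlier Analysis for
    Hybrid Lineages
Version: 0.1.0
Authors@R:
    person("Mosaicscan", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genetic scans for lineages with mosaic
    ancestry: ABBA-BABA style introgression statistics (Patterson's D and
    the symmetric f_dM), nucleotide diversity, absolute (D_XY) and relative
    (F_ST) divergence, exact topology weighting of neighbor-joining window
    trees with majority-topology segmentation and block-bootstrap genome
    proportions, branch-specific dN/dS by parsimony counting, and a
    gene-centered outlier scan that regresses each statistic on local
    recombination rate and flags genes by Cook's distance, with chi-square
    enrichment and permutation tests against a candidate gene list. Ships a
    fully self-contained synthetic-genome generator with known truth for
    end-to-end validation, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
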