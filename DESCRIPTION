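Package: yrscan
Title: Structural Annotation and Classification of Tyrosine-Recombinase Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies tyrosine-recombinase (YR) retrotransposons
    (DIRS and Ngaro superfamilies) in nucleotide assemblies. Scans six-frame
    conceptual translations with position-specific scoring profiles for the four
    diagnostic protein domains (reverse transcriptase, RNase H, tyrosine
    recombinase, DNA N-6-adenine methyltransferase), merges frame-split hits
    into element cores, resolves element boundaries from the two diagnostic
    terminal-repeat architectures (inverted terminal repeats for DIRS, split
    direct repeats A1-core-B1-A2-B2 for Ngaro), assigns superfamily,
    completeness and clade, clusters elements into families by greedy identity
    clustering, builds all-vs-all similarity graphs, and summarises family
    representatives with neighbor-joining trees on concatenated domain
    alignments. A synthetic-genome generator with full truth annotations makes
    every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
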