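Package: cobascan
Title: Phage Genome Termini, Read Recruitment and Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the comparative genomics of lytic marine phages with
    short direct terminal repeats (DTRs), built around the analysis chain used
    for cobamide-dependent roseophages ("cobaviruses"): detection of direct
    terminal repeats and genome reorientation to the DTR 5' end,
    identity-filtered metagenomic read recruitment with breadth-of-coverage
    presence calls and per-gigabase relative abundance, all-versus-all protein
    similarity graphs partitioned with Markov clustering, rho-independent
    transcriptional terminator scanning with a transparent stem-loop stability
    model, and fragment-based nucleotide identity with OPTSIL-style F-linkage
    clustering for species delineation. A synthetic-community simulator with
    planted ground truth (genomes, DTRs, bidirectional terminators, read
    libraries with controlled error rates) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    rtracklayer,
    data.table,
    igraph,
    jsonlite,
    withr,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
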