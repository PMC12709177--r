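Package: nrnbkit
Title: Classification and Biochemical Polarity Analysis of Standalone
    DHH-DHHA1 Nanoribonucleases
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the NrnB family of standalone DHH-DHHA1
    nanoribonucleases. Identifies standalone DHH-DHHA1 proteins by
    motif-signature scanning and motif-anchored domain segmentation,
    reduces redundancy by greedy identity clustering, builds progressive
    multiple alignments with a self-contained affine-gap aligner, filters
    gap-rich columns, infers neighbor-joining trees with midpoint rooting
    and bootstrap support, extracts major clades, computes per-column
    entropy and sequence-logo matrices, and classifies sequences into the
    NrnB-A/B/C clades from diagnostic architecture features (signature
    residue at a reference-anchored position, linker length, C-terminal
    tail length and charge). Also models exoribonuclease degradation
    ladders with non-cleavable linkages, infers degradation polarity from
    substrate/intermediate pairs, normalizes depletion traces, and fits
    phosphate standard curves. A synthetic-data generator evolves
    three-clade protein families along simulated trees so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
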