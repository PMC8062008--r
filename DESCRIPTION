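Package: recscan
Title: Triplet-Scan Detection and Removal of Recombination Signals in
    Nucleotide Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes recombination events in multiple
    nucleotide sequence alignments by exhaustive triplet scanning with
    windowed informative-site profiles and binomial significance, vets each
    signal with the pairwise homoplasy index (PHI) test, the Hudson-Kaplan
    four-gamete test and a misalignment heuristic, tests detected breakpoint
    distributions against genome annotations (coding versus non-coding,
    per-gene, gene edges versus interiors), and emits recombination-free
    alignments in four modes (recombinant removal, fragment masking,
    recombinant splitting, breakpoint partitioning) together with
    codon-aware gene alignments and per-partition neighbour-joining trees.
    A bundled simulator generates clonal alignments on random Yule trees and
    implants mosaic events with exact ground truth, so every statistical
    property can be tested without external data. A command-line front end
    automates the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    phangorn,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
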