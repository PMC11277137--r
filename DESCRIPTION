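Package: alring
Title: Minimal RNA Rings, the AL Sequence, and Pentamer Proximity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing candidate primordial RNA rings. Enumerates
    minimal circular nucleotide sequences whose overlapping codons cover all
    twenty amino-acid synonymy classes of the standard genetic code (pruned
    depth-first search with a compiled kernel), computes circular Hamming,
    edit and permutation distances with medoid (barycenter) selection, folds
    rings into stem-loop hairpins and derives the head pentamer set, extracts
    conserved tRNA-loop motifs and assembles the 22-nt AL ring from the
    19-nt loop consensus, and scores arbitrary sequences for pentamer
    enrichment against a uniform null (the PpAL proximity statistic, with a
    Poisson/Gaussian tail model). A synthetic-sequence generator (uniform
    null and planted-enrichment modes) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
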