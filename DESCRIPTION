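Package: cdbg
Title: Compacted de Bruijn Graph Construction from Reads and References
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs the compacted de Bruijn graph (the set of maximal
    unitigs) and maximal vertex-disjoint path covers from FASTA/FASTQ reads
    or reference sequences. Edges, the distinct canonical (k+1)-mers with
    abundance at or above a solidity threshold, are enumerated with a
    minimizer-partitioned sort-and-count; vertices are associated to
    per-vertex finite-automaton states through a BBHash-style minimal
    perfect hash table using roughly 10 bits per distinct k-mer; maximal
    unitigs are then stitched together by piecewise graph traversals that
    never materialise the ordinary graph. Includes brute-force reference
    implementations and synthetic read/genome generators used as ground
    truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stringi,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
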