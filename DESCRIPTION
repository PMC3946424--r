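Package: palinclip
Title: Detection, Clipping and Simulation of Terminal Interrupted
    Palindrome Artifacts in Degraded-DNA Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequencing libraries built from highly fragmented (historic or
    ancient) DNA can carry an artifact in which the 3' end of a read is a
    perfect reverse complement of its 5' end, separated by intervening
    sequence -- an "interrupted palindrome".  The terminal section is an
    artificial polymerase fill-in templated by the 5' end of the same
    strand after hairpin-loop formation in single-stranded DNA, and it
    inflates mismatch rates at the 3' end, suppressing alignment of
    endogenous reads.  palinclip detects these palindromes, quantifies
    their abundance, clips them from the 3' end, merges overlapping
    paired-end reads, and provides a generative simulator of the
    hairpin-loop library-preparation mechanism with per-molecule ground
    truth, together with a small exhaustive read mapper and library-level
    summaries for validating the detector against simulated data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
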