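Package: stress5p
Title: Quantifying Stress-Induced Loss of 5' mRNA Binding by Scanning
    Initiation Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for measuring how scanning
    translation initiation factors (eIF4A, eIF4B, Ded1) lose 5' mRNA binding
    during glucose starvation and heat shock in budding yeast. Implements
    CRAC read preprocessing (demultiplexing, adapter and quality trimming,
    UMI-based PCR-duplicate collapsing, low-complexity filtering), exact-match
    alignment with random multi-mapper assignment, transcript-level total and
    5'-end binding quantification with pseudocounted RPM normalization,
    start-codon metagene profiles and 5'-versus-pervasive binding statistics,
    spike-in-anchored RNA-seq abundance changes with regulon summaries, and
    SILAC TRAPP time-course analysis (replicate filtering, fold-change
    classification, PCA). A synthetic-data module generates toy genomes,
    CRAC and two-species RNA-seq reads, and SILAC ratio matrices with known
    ground truth, so every statistic can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
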