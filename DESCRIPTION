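Package: adotrim
Title: Allele Drop-Out Aware Primer Trimming and Two-Round Variant
    Calling for Amplicon Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for managing allele drop-out (ADO) artifacts in
    amplicon-based targeted resequencing. Implements a two-round
    analysis: primer-prefix trimming (one mismatch, no gaps), local
    alignment of reads to their expected amplicon, pileup-based
    allele-fraction variant calling, removal of reads from amplicons
    whose primer footprints carry a round-one variant, re-calling, and
    merging. Also provides a single-round soft-clip baseline emulating
    the vendor amplicon workflow, an untrimmed-alignment mode, a
    synthetic ADO read simulator with planted ground truth, and
    coverage/QC reporting.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
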