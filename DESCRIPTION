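Package: isocorr
Title: Isoform-Aware Self-Correction of Transcriptome Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-correction of noisy third-generation transcriptome long
    reads that preserves isoform diversity. Overlapping reads are recruited as
    evidence for each template read, pairwise alignments are normalised so
    that every mismatch becomes a deletion plus an insertion, and a sliding
    window masks low-identity alignment stretches (typically evidence from a
    different exon structure) with 'N'. A per-position consensus table with a
    dedicated skip statistic separates structurally divergent positions from
    ordinary sequencing error, the template is partitioned into simple areas
    (list-voting consensus) and complex areas (max-weight path through a
    directed acyclic alignment graph, with masked evidence removed), and the
    per-area consensus sequences are merged into the corrected read. Includes
    a windowing-disabled baseline mode, a multi-isoform read simulator with
    per-read ground truth, and evaluation reports for per-base error rates and
    isoform retention binned by relative coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    parallel,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
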