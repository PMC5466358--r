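Package: circbench
Title: Simulation and Benchmarking of Circular RNA Back-Splice Junction Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired-end RNA-seq reads from circularized spliced
    transcripts, including rolling-circle fragment geometry and back-splice
    junction truth accounting, together with a linear-mRNA background read
    generator. Provides the benchmarking methodology used to compare
    back-splice junction callers: sensitivity/precision/F1 at a junction-read
    support threshold, threshold-swept precision-recall curves with
    trapezoidal AUC, pairwise method-overlap proportions, depth-normalized
    RNase R depletion/enrichment classification with top-N summaries,
    read-level sensitivity matrices with average-linkage clustering, and
    recovery of experimentally validated circRNAs. A deterministic fixture
    generator builds toy genomes, annotations and circRNA lists so every
    pipeline stage runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
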