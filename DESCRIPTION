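Package: p53mirnet
Title: Identification and Regulatory Network Analysis of p53-Regulated
    MicroRNAs from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising transcription-factor-regulated
    microRNAs from small RNA sequencing count data. Cleans raw small-RNA
    reads and summarises length and nucleotide composition, quantifies
    mature miRNAs with a mismatch-tolerant matcher, tests differential
    expression between two libraries with the exact Audic-Claverie count
    test, applies robust replicate-consistency selection criteria, infers
    miRNA transcription start sites and strand-aware promoter windows,
    intersects promoters with ChIP-seq peaks, integrates predicted and
    validated miRNA target sets, performs local hypergeometric functional
    enrichment, and assembles a typed TF-miRNA-gene regulatory network from
    which miRNA-mediated feed-forward loops are enumerated. A seeded
    synthetic-data generator with recorded planted truth produces every
    input the pipeline consumes, so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    fgsea,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
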