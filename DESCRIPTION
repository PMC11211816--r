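Package: metassembler
Title: Meta-Assembly of Transcripts from Multiple RNA-Seq Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles full-length transcripts jointly from many bulk or
    single-cell RNA-seq samples. Builds a weighted splice graph per sample
    and gene locus, clusters graphs across samples by splice-position
    similarity, bridges paired-end fragments in two stages (first against
    the sample's own graph, then against the cluster's combined graph, so
    junctions missed in one sample can be restored from the others),
    decomposes every graph into candidate transcripts with a
    phase-preserving vertex-decomposition algorithm guided by per-sample
    edge-support vectors, scores candidates with a 50-feature random
    forest, and aggregates identical intron chains into scored
    meta-transcripts. Includes a spliced-alignment simulator and an
    intron-chain-matching evaluation harness (precision/recall curves and
    partial AUC).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    digest,
    jsonlite,
    ranger,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
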