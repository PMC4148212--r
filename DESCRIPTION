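Package: corepeak
Title: Replicate-Concordant ChIP-seq Peak Analysis for Co-repressor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of co-repressor ChIP-seq experiments:
    replicate-concordant peak selection by maximum percent overlap of
    p-value-ranked peak lists, high-confidence peak supersets, peak-width and
    proximity-clustering statistics, strand-aware annotation of peaks to
    transcripts with summit-to-TSS distances, chromatin-class enrichment of
    summit windows, upper-quantile normalization of binned coverage tracks,
    anchored meta-profiles and heatmap matrices, and promoter-proximal RNA
    polymerase II pause ratios with decile enrichment. Includes a seeded
    synthetic-data generator that emits replicate peak lists, coverage tracks
    and chromatin segmentations with ground-truth manifests so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
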