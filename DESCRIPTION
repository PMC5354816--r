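Package: bivalency
Title: High-Confidence Bivalent Chromatin Regions and Their Integration
    with DNA Methylation and Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls high-confidence bivalent, H3K4me3-only and H3K27me3-only
    chromatin regions from multi-cell-line ChIP-seq peak sets, annotates them
    against CpG islands, promoters, repeats and enhancers, partitions bivalent
    regions into transcription-factor occupancy clusters, and integrates the
    resulting chromatin categories with Infinium methylation-array and RNA
    expression data, including empirical-Bayes moderated-t differential
    methylation, CIMP-stratified analyses and pan-cancer recurrence. Includes
    a seeded synthetic-data generator with planted truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, ChIPSeq, DNAMethylation, DifferentialMethylation,
    Clustering, GeneExpression
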