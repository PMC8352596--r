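Package: methdyn
Title: DNA Methylation Dynamics: Differential Methylation, Metagene
    Profiles, and Co-Expression Analysis for Plant Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-alignment analysis of whole-genome bisulfite sequencing
    methylomes across developmental series and genotypes, modelled on
    Arabidopsis embryogenesis studies. Calls differentially methylated
    cytosines with a root-mean-square contingency-table statistic under an
    exact or Monte-Carlo margin-fixed permutation null with
    Benjamini-Hochberg control, collapses them into differentially
    methylated regions, computes weighted methylation over regions,
    metagene (flank-body-flank) profiles, and centromere-distance
    percentile summaries, partitions genes by methylation-difference
    profiles with k-means, ranks genes by Euclidean distance to a seed-set
    expression centroid against a permutation baseline, and tests DMR-gene
    associations for enrichment. Ships seeded generators for synthetic
    genomes, methylomes and expression matrices with planted effects so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
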