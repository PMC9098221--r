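Package: bivalscape
Title: Promoter Chromatin State Classification and Differential Occupancy
    Analysis for CUT&RUN and ATAC-Seq Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of chromatin occupancy and accessibility
    around transcription start sites (TSSs). Builds a deduplicated
    promoter-TSS catalog from refGene-style gene tables, quantifies
    bedGraph coverage tracks in windows and binned metaprofiles,
    classifies promoters into H3K4me3-Low, H3K4me3-Only and bivalent
    states by quartile thresholds, partitions the TSS neighbourhood into
    upstream/center/downstream subregions bracketing the -1/+1
    nucleosomes and the nucleosome-free region, assigns five-cluster
    labels from combinatorial fold-changes in remodeler occupancy upon
    knockdown, performs peak-set algebra (merging, nearby assignment,
    equal High/Low splits, annotation enrichment), links peaks to
    differentially expressed genes, and ships a synthetic chromatin
    simulator with ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
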