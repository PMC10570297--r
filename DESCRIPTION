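Package: cnvrscan
Title: CNV Filtering, CNVR Merging and Vst Differentiation Scans for
    Multi-Group Read-Depth Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population analysis of copy number variation from
    read-depth callers. Parses CNVnator-style per-sample call files,
    applies the standard significance/size/mapping-quality filter, merges
    overlapping calls across samples into copy number variable regions
    (CNVRs), genotypes normalized copy number per CNVR and sample,
    classifies states on the Redon deleted/conserved/duplicated scale,
    scans for between-group differentiation with the Vst statistic and a
    top-quantile candidate selection, and classifies CNVRs against gene
    models (exonic, intronic, upstream, downstream, intergenic). Includes
    a synthetic multi-group cohort simulator with known truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
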