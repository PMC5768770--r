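Package: clonarch
Title: Clonal Architecture of Multi-Region Tumor Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the clonal architecture of solid tumors
    from multi-region (multi-sector) sequencing data. Implements post-caller
    somatic variant filtering and targeted deep-sequencing validation rules,
    per-patient binary presence matrices with trunk/branch/private mutation
    classification and proportional intra-tumor heterogeneity (pITH),
    neighbor-joining phylogenies from Hamming distances, allele-specific
    copy-number instability indices (GII and adGII) with gene/cytoband
    assignment and LOH detection, a simulation-based whole-genome-doubling
    test with ploidy-dependent thresholds, cancer-cell-fraction estimation
    with early/late mutation timing, a driver-gene dominance score, and a
    synthetic multi-sector tumor cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
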