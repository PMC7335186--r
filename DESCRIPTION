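Package: debrisEM
Title: Ambient RNA Debris Filtering for Droplet-Based Single-Nucleus
    RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and removes droplets contaminated with ambient
    (extranuclear) RNA from droplet-based single-nucleus and single-cell
    RNA-seq count matrices. Droplet expression is modelled as a mixture of
    multinomials over debris and cell-type components, fitted by
    semi-supervised expectation maximization in which low-count droplets
    are held fixed in the debris component. Per-droplet debris scores are
    derived from debris-enriched genes and used to filter contaminated
    droplets. Also provides the barcode-rank quantile-threshold baseline
    filter, contamination metrics (percent spliced, mitochondrial and
    MALAT1 UMI fractions, two-Gaussian midpoint classification), and a
    seeded simulator of droplet count matrices with known ambient
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    knitr
biocViews: SingleCell, Transcriptomics, QualityControl, Preprocessing,
    Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
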