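Package: spikemap
Title: Cross-Modal Integration of smFISH Spatial and Single-Cell RNA-Seq Data
    from Developing Cereal Spikes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates targeted single-molecule FISH (smFISH) spatial
    transcriptomics with whole-transcriptome single-cell RNA-seq of developing
    grass inflorescences. Provides cosine k-nearest-neighbour imputation of
    genome-wide expression into spatially anchored cells, reverse projection of
    spatial cluster labels onto single cells with percent-contribution
    matrices, informative-gene filtering and Pearson correlation of cluster
    profiles within and across studies (including homeolog aggregation for
    polyploid wheat), one-vs-rest marker detection with strict and relaxed
    filters, a mean-plus-four-standard-deviations co-expression screen,
    protoplasting-artifact detection, spot-density quantification in
    delineated tissue regions with between-stage tests, and Tukey-based
    region-of-spike expression assignment with chi-square enrichment. A
    seeded synthetic paired-modality generator with known ground truth makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
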