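Package: gatefinder
Title: Discovery and Calibration of Surface-Marker Gating Panels for
    Rare Progenitor Purification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and calibrating flow-cytometry gating
    panels that purify rare colony-forming progenitors (such as
    megakaryocyte progenitors) from index-sort data, and for projecting
    single-cell RNA-seq query cells onto an annotated reference with a
    calibrated rejection threshold. Implements colony-outcome scoring of
    index-sorted wells, replicate cleaning and rank normalization, SMOTE
    class augmentation, bagged decision trees with a depth-first
    first-occurrence rank importance statistic, sequential binned
    cumulative-enrichment curves with knee-point cutoff selection,
    ROC-power marker-gene selection, random-forest cell-type projection
    with a negative-control-calibrated assignment threshold, single-cell
    QC filters, and synthetic-data generators that emulate the assumed
    statistical structure of index-sort and single-cell inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    randomForest,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
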