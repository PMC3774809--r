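Package: woundtrack
Title: Cell Tracking and Wound-Healing Image Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies keratinocyte behaviour in time-lapse microscopy and
    wounded-tissue sections. Provides nuclei segmentation (top-hat filtering,
    region-adaptive thresholding, watershed splitting of nuclear clusters),
    cost-based frame-to-frame cell tracking with mitosis detection, trajectory
    break merging and lineage trees, single-cell motility statistics (speed,
    moving-angle distributions, mean square displacement, persistence),
    scratch-assay kinographs with gap-coverage and closure-speed estimation,
    and marker-positivity scoring of wounded epithelium partitioned into
    regions. Ships synthetic ground-truth generators for motility movies,
    scratch assays and stained tissue sections so every stage can be
    benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
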