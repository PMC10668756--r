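Package: cometseg
Title: Comet Assay Image Segmentation and DNA-Damage Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation and quantification of single-cell gel
    electrophoresis (comet assay) fluorescence micrographs. Implements a
    four-stage pipeline (morphological preprocessing, threshold-based
    candidate location, head segmentation under shape constraints, convex
    hull tail delimitation), a four-feature decision-tree classifier that
    separates tailed comets from undamaged head-only cells, geometric
    discard rules, and tail-moment quantification. Includes a synthetic
    ground-truth image generator for end-to-end validation, an evaluation
    harness (detection rate, head and tail intersection-over-union), and
    the downstream statistical toolkit: tie-corrected Spearman rank
    correlation, one-breakpoint segmented (broken-line) linear regression
    with Wald slope intervals, and ridgeline-style per-group kernel
    density summaries. Ships a 30-record sperm-viability table for the
    spider crab Maja brachydactyla as a worked dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    rpart,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
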