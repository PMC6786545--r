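Package: crowdseg
Title: Evaluation of Crowd-Sourced Medical Image Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating segmentations of anatomy drawn by panels of
    annotators (citizen scientists and experts) as point-outline polygons.
    Outlines are rasterized to pixel masks with a scanline fill, fused into
    per-pixel consensus maps and majority-vote consensus segmentations, and
    scored with the Dice similarity coefficient, both for individuals against
    a reference panel and panel-against-panel. Companion analyses cover
    annotator throughput (Mann-Whitney U with exact enumeration at small n),
    outline point counts versus workload (Pearson correlation), and covariate
    effects on accuracy. A synthetic-study generator produces vertebra-like
    ground-truth shapes and panels of imperfect annotators with configurable
    boundary noise, bias, point budgets and workloads, so the whole pipeline
    can be exercised and validated without access to any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
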