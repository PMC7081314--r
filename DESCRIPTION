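Package: ttaseg
Title: Test-Time Augmentation for Microscopy Segmentation
Version: 0.1.0
Authors@R:
    person("ttaseg", "maintainers", email = "ttaseg@example.org",
           role = c("aut", "cre"))
Description: A predictor-agnostic test-time-augmentation engine for
    microscopy segmentation. Augments a test image with the six dihedral
    transforms used for nuclei segmentation (identity, horizontal and
    vertical flips, 90/180/270 degree rotations), collects per-view
    predictions from a pluggable predictor, reverts each prediction to the
    original frame (dis-augmentation), and merges the views: probability
    averaging with thresholding for semantic segmentation, and an
    instance-aware IoU-matching plus majority-voting algorithm for instance
    segmentation. Includes the Data Science Bowl style mean average
    precision over IoU thresholds, pixel-level IoU, paired merged-versus-
    original comparison with a Wilcoxon signed-rank test, and a seeded
    synthetic nuclei-scene simulator so the whole pipeline is testable
    without trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
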