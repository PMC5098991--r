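Package: roboshoal
Title: Binary-Choice Assay Analysis for Robotic Fish-Replica Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end analysis pipeline for zebrafish binary-choice
    experiments with a robotically actuated fish replica: synthetic
    generation of mode-switching fish trajectories and replica waypoint
    programs, three-dimensional trajectory reconstruction from two
    orthogonal camera views (background subtraction, blob detection,
    nearest-neighbour track linking, moving-average smoothing,
    cross-correlation synchronization), spatial-preference, shoaling and
    kinematic metrics, histogram transfer-entropy estimation of directional
    fish-stimulus interaction with wavelet denoising and segment gating,
    and the accompanying statistical battery (IQR outlier screening,
    one-sample t-tests against chance, one-way ANOVA with Tukey HSD,
    direction-by-segment ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    withr
Config/testthat/edition: 3
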