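Package: gaitscore
Title: Video-Derived Gait Features and Ordinal Models of Parkinsonism Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing parkinsonism severity in gait from pose-tracking
    output. Reads 2D pixel keypoints (OpenPose/MPII dialect) and 3D metric joint
    trajectories (Kinect-style 25-joint skeleton) for walking bouts, detects foot
    strikes from ankle vertical velocity (35%-of-cycle-peak rule), and computes
    eight 2D and sixteen 3D spatiotemporal, variability, symmetry and
    margin-of-stability gait features. Severity scores on 0-4 ordinal clinical
    scales (UPDRS-gait, SAS-gait) are modelled by univariate proportional-odds
    screening, Pearson-correlation collinearity pruning, and multivariate
    proportional-odds regression with age and sex, with confusion-matrix and
    per-participant accuracy reporting. A synthetic gait and cohort generator
    with full ground truth makes every stage testable without clinical video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    zoo,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
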