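Package: cellshift
Title: Mean-Shift Tracking of Unlabeled Cells in 3D Time-Lapse Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tracks large populations of unlabeled cells in
    time-lapse 3D phase-contrast volumes. Each volume is cross-correlated
    with a cell template (FFT template matching) so that cells become smooth
    correlation blobs; a soft maximum filter detects every distinguishable
    peak; one flat-kernel mean-shift tracker per cell follows its peak from
    frame to frame; tracker collisions are detected and resolved (including
    removal of short-lived "parasite" trackers) so that trajectories stay
    valid when cells touch, divide, enter or leave the field. Trajectories
    are summarized by duration-normalized migration descriptors (average
    speed, maximum relative distance from origin) and compared across
    experimental conditions with a rank-based k-sample test. A seeded
    synthetic scene generator renders ground-truthed sequences so the whole
    pipeline can be benchmarked without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
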