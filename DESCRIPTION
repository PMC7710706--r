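Package: walkback
Title: Quantification of Backward Walking in Drosophila from Pose,
    Calcium Imaging, and Arena Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end quantification pipeline for studies of
    descending control of backward walking in Drosophila melanogaster.
    Converts pose-tracking tables (DeepLabCut CSV dialect) into leg
    joint angles, detects swing peaks, segments and aligns step cycles,
    and computes step-geometry metrics (anterior, posterior and dorsal
    extreme positions, step size, swing-stroke amplitude, joint-angle
    ranges, flexion slopes, step frequency). Scores interleg
    coordination from footfall patterns via a co-swing index. Maps
    stimulus responses in volumetric calcium imaging by per-voxel
    lagged cross-covariance against a GCaMP response kernel, producing
    activated and inhibited voxel maps, and computes ROI dF/F0 traces.
    Quantifies forward and backward walking distances from arena
    centroid tracks using heading-projected speed. A synthetic-data
    module generates pose, calcium, and arena datasets with fully
    known ground truth so that every stage of the pipeline can be
    validated without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
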