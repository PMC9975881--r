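Package: adosmotion
Title: Movement Features and Activity-Level Correlation from 2D Pose Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies children's activity level from multi-person 2D skeleton
    streams recorded during ADOS (Autism Diagnostic Observation Schedule)
    assessments. Reads OpenPose BODY_25 keypoint JSON, selects the participating
    child among multiple detected people with a nearest-neighbour gating filter,
    computes pixel-distance (PD) and instantaneous-pixel-velocity (IPV) movement
    features per activity segment, and correlates the features with clinician
    activity-level scores using Spearman correlation with Benjamini-Hochberg
    correction, Pearson redundancy analysis, and a Fisher-z correlation power
    analysis. Includes a synthetic cohort generator emulating score-dependent
    motion so the full pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
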