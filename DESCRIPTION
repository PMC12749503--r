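Package: kinescore
Title: Action Scoring for Physical-Therapy Movement Analysis from Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing rehabilitation exercises from markerless
    human-pose keypoint time series (33-landmark topology). Reads and writes
    structured pose JSON, stabilizes keypoints with a fixed maximum bounding
    box, extracts joint angles, range of motion and angular velocity, segments
    and counts exercise repetitions from angle trajectories via peak/trough
    detection, aligns user and reference motion with dynamic time warping,
    scores per-repetition similarity with normalized cross-correlation, and
    produces a composite Action Score with clinician-style deviation feedback.
    Includes a seeded planar forward-kinematics motion simulator so that every
    stage of the pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
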