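Package: actitree
Title: Thigh-Accelerometer Activity-Type Classification for Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies sitting, standing, moving, walking, running and
    biking from raw thigh-worn triaxial accelerometry using a five-node
    decision tree on 2-second, 50%-overlap window features (longitudinal
    standard deviation, maximum per-axis standard deviation, thigh
    inclination and forward/backward angle), with child-calibrated and
    adult threshold presets, per-activity median-filter label smoothing,
    priority-rule resolution of multiple assignments, and optional lying
    detection from a trunk sensor. Includes device-orientation handling
    for two thigh placements, anti-aliased rational resampling to the
    method's 30 Hz working rate, second-by-second evaluation against a
    timestamped activity log (per-activity sensitivity and specificity,
    label composition of complex activities, pooled class-conditional
    feature densities), and a kinematic synthetic-signal generator that
    emulates a structured activity protocol so the full pipeline is
    testable without field recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
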