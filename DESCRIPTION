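Package: cprmeter
Title: Video-Based Measurement of Chest-Compression Quality with a Fixed-Length Marker Wristband
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing cardiopulmonary-resuscitation (CPR) quality
    from monocular video. A fixed-length fluorescent marker wristband worn by
    the rescuer calibrates a pinhole-camera depth mapping that converts the
    pixel displacement of a tracked detection box into real-world compression
    depth; a peak-trough cycle detector yields compression count and
    frequency; keypoint rules flag common posture faults; and a lightweight
    anchor-based detector (ShuffleNetV2 backbone, small-target feature
    pyramid, mixed local channel attention, partial convolutions) localises
    the wristband, with parameter/FLOP accounting and mean-average-precision
    evaluation. A synthetic-scene generator produces marker trajectories,
    rendered frames with labels, and posture keypoint fixtures with ground
    truth, so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
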