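Package: harload
Title: Activity Recognition and Heart-Rate Workload Scoring for Wearable Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for real-time physical-workload tracking from body-worn
    sensors: one-second windowed statistical feature extraction from hip-worn
    triaxial accelerometry (20 Hz), a random-forest human-activity classifier
    with Gini-importance feature pruning and a k-nearest-neighbour baseline,
    Frimat's-criterion workload scoring from wrist heart-rate streams, and a
    synthetic session generator emulating five exercise activities so the full
    pipeline can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
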