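Package: actisleep
Title: Sleep, Sleep-Stage, Nonwear and Nap Classification from Raw Wrist
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies sleep and wake, device nonwear, sleep stages and
    daytime naps from raw tri-axial wrist accelerometer recordings scored
    on a 30-second epoch grid. Implements the derived signals ENMO
    (Euclidean norm minus one), z-angle and LIDS (locomotor inactivity
    during sleep); a 39-column epoch feature matrix of simple statistical
    measures; the van Hees posture-angle heuristic and the Sadeh and
    Cole-Kripke count-based baselines; a SMOTE-balanced, participant-
    grouped nested cross-validation protocol for random forests with
    5-minute probability smoothing and outer-fold ensembling; a
    hierarchical (local classifier per parent node) sleep-stage
    classifier with hierarchical precision/recall/F1; and nap-episode
    extraction outside the sleep-period time window. A synthetic
    labelled-recording generator provides desk-scale test data with the
    statistical structure the classifiers assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
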