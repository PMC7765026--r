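Package: glowsel
Title: Sensor Selection for Multi-Sensor Activity Recognition by Binary
    Glowworm Swarm Ensemble Pruning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds wearable-sensor human activity recognition (HAR)
    ensembles in which every sensor source drives one extreme learning
    machine (ELM) classifier, the member decisions are fused by majority
    voting, and the deployed sensor subset is chosen by an improved binary
    glowworm swarm optimizer with a bulletin board, probabilistic bit-wise
    moves, a three-candidate composite search and a decaying mutation rate.
    Includes sliding-window statistical feature extraction, missing-data
    repair, leave-one-subject-out evaluation, an exhaustive subset oracle
    for small pools, and a synthetic multi-subject recording generator with
    known informative sensors so the whole pipeline is testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
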