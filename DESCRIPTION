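Package: imitatebci
Title: Closed-Loop Brain-Computer Interface Decoder Training by Online
    Imitation Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates closed-loop training of brain-computer interface
    (BCI) decoders as an online imitation-learning problem.  Provides
    effectors (a 3D cursor and an articulated kinematic chain standing in
    for an arm), goal-directed intention oracles (straight-line cursor
    oracle and a damped-least-squares resolved-rate controller for the
    chain), a linear-Gaussian synthetic neural encoding model with
    signal-to-noise calibration, a steady-state velocity Kalman filter
    decoder fit by ridge regression, three online parameter-update rules
    (online gradient descent, moving average / smoothBatch, and
    follow-the-leader with an exact recursive-least-squares executor),
    dataset-aggregation closed-loop sessions with assisted (oracle-blended)
    decoding, empirical regret analysis against the best decoder in
    hindsight, encoding-model recovery curves, and intention model-mismatch
    studies (random intention noise, fixed linear operators, and
    distance-dependent arc rotations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
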