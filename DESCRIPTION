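Package: capfuse
Title: Feature-Level Fusion of Multichannel EEG Time Series for CAP A-Phase
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Second-by-second detection of cyclic alternating pattern (CAP)
    A phases from multichannel sleep EEG by feature-level fusion: each channel
    feeds a recurrent (LSTM or bidirectional LSTM) branch, branch features are
    concatenated and classified by dense plus softmax layers trained with
    cost-sensitive Adam. The branch/fusion architecture is encoded as a 15-bit
    genome and searched either by a genetic algorithm (tournament-of-two
    selection, two-point crossover, scheduled bit-flip mutation, two-elite
    survival) or by discrete binary particle swarm optimization (ring topology,
    time-varying inertia, sigmoid position sampling). Includes Chebyshev
    anti-alias resampling to 100 Hz, per-second windowing, ROC-optimal
    thresholding with isolated-label post-processing, two-fold and
    leave-one-subject-out evaluation protocols, channel-loss and additive
    white Gaussian noise robustness sweeps, and a seeded generator of CAP-like
    synthetic recordings for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
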