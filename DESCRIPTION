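Package: serialshift
Title: Serial Dependence in Working Memory: Behavioral Bias Fitting and
    Inverted Encoding Model Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying serial dependence in delayed-estimation
    working memory experiments. Fits the first-derivative-of-Gaussian (DoG)
    model of attractive response biases toward the previous trial's target,
    with profile-likelihood estimation, participant-level sign-flip permutation
    tests and data-point bootstrap. Reconstructs feature (motion direction)
    information from multi-sensor neural recordings with an inverted encoding
    model (18 direction-tuned channels, shifted-basis averaging, cross-session
    cross-validation), and tests reconstruction fidelity, attractive shifts of
    the reconstructed direction (clockwise/counter-clockwise flip-and-average),
    participant-resampling bootstrap inference, cluster-based sign-flip
    permutation tests over time, and circular brain-behavior correlations.
    Includes a synthetic-data generator that emulates the balanced two-item
    retro-cue task design and direction-tuned sensor epochs, so the full
    analysis chain is testable end to end without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
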