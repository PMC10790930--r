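Package: errpRL
Title: Error-Related Potential Decoding and Human-Feedback-Guided
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for brain-computer-interface
    driven robot training. Generates synthetic multichannel EEG carrying
    error-related potentials (a frontocentral N200 followed by a delayed
    positivity), implements the full offline decoding pipeline (IIR notch and
    band-pass filtering, common average reference, epoching, baseline
    correction), four classifier families (time-domain features with LDA or
    RBF-SVC, an xDAWN/tangent-space Riemannian classifier, and a compact
    depthwise/separable convolutional network), bootstrap confidence-interval
    statistics for model and SNR comparison, and a discretized 3-D navigation
    environment with an A* optimal-action oracle in which a human-feedback
    policy learned from noisy or BCI-decoded evaluative feedback guides the
    exploration of a discrete-action deep deterministic policy gradient agent,
    evaluated with success weighted by path length (SPL).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    MASS,
    pROC,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
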