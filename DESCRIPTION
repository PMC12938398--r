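Package: sleepgcn
Title: Sleep Stage Classification with Dual-Scale Connectivity Graph Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic sleep stage classification from multichannel
    polysomnography using dynamic dual-timescale functional-connectivity
    graphs, multi-scale morphological convolution branches with
    self-attention, adaptive spatio-temporal Chebyshev graph convolution
    with mixture-of-experts fusion, and adversarial subject-invariant
    training through a gradient-reversal layer. Includes a synthetic
    polysomnography generator with stage-dependent spectral signatures,
    transient events (spindles, K-complexes), inter-channel propagation
    lags and subject-level baseline shifts, EDF/CSV input-output, epoch
    segmentation, subject-wise splitting, and the standard evaluation
    metrics (confusion matrix, per-class precision/recall/F1, macro F1,
    Cohen's kappa). Gradient-based training is driven by a small built-in
    reverse-mode automatic-differentiation tape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), caret, jsonlite, yaml, MASS, nnet, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
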