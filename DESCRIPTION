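Package: epitensor
Title: Feature-Tensor Epileptic Detection from Directed EEG Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds directed functional brain networks from multichannel EEG
    by transfer entropy, attacks them with receiving-edge and sending-edge
    removal to obtain residual-network feature curves (average clustering
    coefficient and network efficiency), assembles per-subject five-way
    feature tensors over a threshold sweep, reduces them to core tensors by
    Tucker decomposition with higher-order orthogonal iteration, and
    classifies subjects with kernel support vector machines under repeated
    stratified k-fold cross-validation. Includes rhythm-band preprocessing
    (notch, resampling, segmentation, wavelet-packet or zero-phase bandpass
    decomposition into beta, alpha, theta and delta bands), group-level
    t-test networks, and a synthetic-data generator producing random graphs,
    coupled binary processes with analytically known transfer entropy, and
    two-cohort EEG-like signal sets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
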