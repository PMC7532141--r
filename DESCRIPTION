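Package: ddxnet
Title: Densely Connected Dilated Causal Convolutional Networks for Clinical Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements DDxNet, a densely connected, adaptively dilated,
    causal 1-D convolutional architecture for diagnosis from time-varying
    clinical data (EEG, single-lead ECG, EHR episode tables), together with
    its modality-specific featurization pipelines (TCP montage and MFCC
    features for EEG, R-peak heartbeat extraction for ECG, uniform-grid
    tensorization for EHR), the training recipe (Adam with cosine warm
    restarts, label smoothing, L2 weight regularization, gradient clipping),
    seeded synthetic-data generators for desk-scale experiments, and the
    evaluation metric suite (confusion-count metrics, f1, micro/macro/
    weighted AUROC). The network engine (causal dilated convolutions,
    pooling, backpropagation) is implemented in base R matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
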