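Package: genegate
Title: Gene-Pattern-Gated Neural Networks for Radiosensitivity and
    Survival Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feedforward neural networks whose first-layer weights are
    gated by a binary selectively connected matrix derived from gene
    similarity (non-negative matrix factorization) or from autoencoder
    bottleneck weights, for predicting cellular radiosensitivity (the
    surviving fraction at 2 Gy) and survival after radiotherapy.
    Includes rank-based per-sample normalization of multi-omics inputs,
    SELU hidden activations, censoring-aware survival losses (negative
    log partial likelihood and a partial quadratic cost), mask-preserving
    full-batch gradient descent, occlusion-based gene importance,
    deep-ensemble epistemic uncertainty, concordance-index evaluation
    with cross-validation, Cohen's kappa validation of the mask against
    a prior gene-interaction network, and a synthetic multi-omics
    generator with planted modular structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
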