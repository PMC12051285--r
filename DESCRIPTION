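Package: aampnn
Title: Atom-Attention Message-Passing Neural Networks with Contrastive
    Pretraining for Molecular Permeability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a directed message-passing neural network over
    molecular graphs with a multi-head atom-attention readout, optional
    extended-connectivity fingerprint (ECFP) concatenation, and
    self-supervised contrastive pretraining by random atom masking with a
    normalized temperature-scaled cross-entropy (NT-Xent) objective.
    Supports binary permeability classification (blood-brain barrier,
    Caco-2), dataset curation with k-means permeability labeling, Murcko
    scaffold diversity and Tanimoto leakage diagnostics, stratified
    splitting and cross-validation, Bayesian hyperparameter search, and
    per-atom attention/occlusion interpretation with heatmap export.
    Molecule parsing, canonicalization and fingerprints are provided by
    ChemmineR/ChemmineOB (OpenBabel); the network forward and backward
    passes are implemented in base R matrix code.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    pROC,
    withr,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
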