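Package: dpfedmil
Title: Differentially Private Federated Multiple-Instance Learning for Histopathology Bags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for privacy-preserving federated
    classification of whole-slide-image feature bags. Provides a synthetic
    generator for multiple-instance bags and multi-hospital cohorts, a mosaic
    bag-preparation stage (tissue masking, grid tiling, patch clustering,
    per-cluster sampling, pluggable feature extraction), a permutation-invariant
    memory-based set classifier with hand-derived gradients, local training by
    plain SGD/Adam or differentially private SGD with per-microbatch clipping
    and Gaussian noise, a Renyi differential-privacy accountant for the
    subsampled Gaussian mechanism, federated averaging with IID and non-IID
    client partitioning, and scaled-down experiment drivers comparing
    federated, non-collaborative and centralized training.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
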