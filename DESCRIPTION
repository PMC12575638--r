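Package: ppfil
Title: Privacy-Preserving Federated Incremental Learning with a Hash-Chained Model Ledger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Single-machine simulator for privacy-preserving federated
    incremental learning on clinical-style tabular data. Provides a synthetic
    tabular data generator with incremental task streams and non-IID client
    partitioning, chaotic bobcat optimisation (CBOA) wrapper feature
    selection, an entropy-sized deep belief network classifier trained by
    contrastive divergence, per-client replay caches ranked by accumulated
    gradient-norm importance, local differential privacy on clipped model
    updates, median/MAD robust filtering with importance-weighted federated
    averaging, a SHA-256 hash-chained model ledger with accuracy-gated block
    admission and proof-of-contribution scoring, and a suite of poisoning
    attack generators for stress-testing the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    glmnet
Config/testthat/edition: 3
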