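Package: transpred
Title: Sequence- and Structure-Based Substrate Prediction for Membrane Transporters
Version: 0.1.0
Authors@R:
    person("Transpred", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature encoders and classifiers for predicting the transported
    substrate of membrane transport proteins from amino-acid sequences,
    3Di structural-state sequences, PSSM conservation profiles and pooled
    per-residue embeddings. Includes Gene Ontology based labeled-dataset
    construction with is_a ancestor propagation, greedy redundancy
    reduction, PCA/isolation-forest consensus outlier detection, a
    class-weighted RBF support vector machine with nested stratified
    cross-validation, a dropout-regularized feedforward neural network,
    and synthetic-data generators so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
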