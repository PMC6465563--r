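Package: bipartiteLP
Title: Bidirectional Label Propagation for Bipartite Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Link prediction on sparse binary bipartite association matrices
    (for example disease-by-microbe tables) using Gaussian interaction
    profile kernel similarity, neighbour-restricted row normalisation, and
    bidirectional label propagation on the two resulting similarity
    networks. Includes leave-one-out and repeated k-fold cross-validation
    with rank-based AUC and ROC curves, parameter-grid sweeps, a synthetic
    block-model generator for benchmarking, ranked prediction output, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), pROC, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'data-io.R'
    'propagation.R'
    'evaluation.R'
    'similarity.R'
    'synthetic.R'
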