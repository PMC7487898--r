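Package: molforge
Title: Graph-Based De Novo Molecular Design with Robust Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: De novo design of small molecules as a reinforcement-learning
    problem on molecular graphs. A directed message-passing neural network
    predicts binding affinities (pKi) from SMILES, trained under a general
    adaptive robust loss whose shape and scale parameters are learned jointly
    with the model, so that grossly mislabelled affinities do not dominate the
    fit. Predicted affinities, drug-likeness (QED), synthetic accessibility and
    adversarial terms are combined into a reward that drives a graph
    convolutional policy network trained with proximal policy optimization to
    assemble molecules bond by bond under valence constraints, including
    multi-objective (dual-target) rewards. Evaluation tools cover Tanimoto
    similarity to a reference set, top-k reporting and Pareto-front extraction.
    Chemistry primitives (SMILES parsing, canonicalization, SMARTS matching,
    fingerprints, descriptors) are provided by ChemmineR/ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
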