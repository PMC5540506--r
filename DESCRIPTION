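Package: rnaFragNet
Title: Non-Coding RNA Classification from Secondary-Structure Fragment
    Features with a Convolutional Network
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies non-coding RNA sequences by their secondary
    structure. Each RNA is represented as a labelled undirected graph
    (nucleotide vertices; covalent backbone and hydrogen-bond base-pair
    edges) built from dot-bracket notation, including extended
    pseudoknot bracket families. Closed frequent connected sub-graphs
    are mined from a training collection under minimum-support and size
    constraints and used as boolean presence/absence features. A small
    convolutional neural network (two convolutional layers with
    logistic activations and max-pooling, followed by a one-hidden-layer
    perceptron) is trained on the boolean vectors by stochastic gradient
    descent. Includes stratified cross-validation with fold-aggregated
    confusion matrices, projection of unseen sequences into a frozen
    feature space, a synthetic labelled-dataset generator with
    class-specific hairpin motifs, a toy base-pair-maximisation folder,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, StructuralPrediction, FeatureExtraction
RoxygenNote: 7.3.3
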