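Package: stackCCC
Title: Stacking-Ensemble Ligand-Receptor Interaction Prediction and
    Cell-Cell Communication Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts ligand-receptor interactions (LRIs) from protein
    sequences and scores cell-cell communication (CCC) between labelled
    cell types in expression data.  Sequences are encoded with four
    descriptor families (amino-acid composition, k-spaced amino-acid
    pairs, composition/transition/distribution, conjoint triads) and
    reduced with principal component analysis; negative training pairs
    are drawn from unlabeled candidates lying outside a centroid-distance
    band; a stacking ensemble of a polynomial-kernel support vector
    machine, a one-dimensional convolutional network and a multi-head
    attention classifier feeds a softmax meta-perceptron that emits
    interaction probabilities.  Filtered interactions are converted to
    sender-receiver communication strengths with three expression-based
    scores combined by PERT three-point estimation.  Includes seeded
    synthetic-data generators, a cross-validation and metrics harness,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    SummarizedExperiment,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
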