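Package: purne
Title: Positive-Unlabeled Gene Function Prediction with Synthetic
    Positives and Representative Negatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts gene function from few annotated positive genes and
    many unlabeled ones. The positive set is enlarged with synthetic
    convex-combination examples, a representative negative set is
    extracted from the unlabeled genes by iterative maximum-margin
    retraining starting from a one-class boundary, and a final classifier
    is selected by grid search. Includes kernel construction and fusion
    for heterogeneous genomic data (Gaussian kernel on imputed expression
    profiles, diffusion kernel on protein-interaction graphs, precomputed
    sequence-similarity matrices), Gene Ontology annotation handling with
    true-path up-propagation, baseline negative-selection strategies, an
    evaluation layer (precision/recall/F1 with the NaN-to-zero convention,
    ROC score, per-group aggregation), and a simulator for
    positive-unlabeled benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
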