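Package: chemont
Title: Structure-Based Chemical Ontology Classification with Machine Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns a structure-annotated chemical ontology (for example
    ChEBI) into supervised classification problems and evaluates machine
    learning approaches for structure-based chemical ontology
    classification. Parses OBO ontologies into subsumption graphs,
    distinguishes classes from structure-bearing leaf members, constructs
    balanced N-by-M datasets by smallest-first non-overlapping sampling,
    encodes SMILES as 1024-bit topological path fingerprints or as
    character-level and atom-grouped token sequences, wraps eight classical
    single-label classifiers, trains a multi-label LSTM network with
    abstention, and scores predictions with precision/recall/F1 and an
    ontology-aware path-length metric between predicted and asserted parent
    classes. A synthetic-fixture generator produces toy ontologies with
    motif-bearing SMILES leaves so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    withr,
    ChemmineOB,
    glmnet,
    class,
    rpart,
    randomForest,
    e1071,
    MASS
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
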