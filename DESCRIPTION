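Package: sarscape
Title: Structure-Activity Landscapes, Activity Cliffs and Multiclass QSAR for Inhibitor Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates IC50 activity tables into pIC50 activity classes, computes
    drug-likeness descriptors and binary substructure fingerprints (MACCS-166 and a
    PubChem-style 881-key set), explores chemical space by univariate tests and PCA,
    builds structure-activity similarity (SAS) maps with SALI-ranked activity cliffs
    and consensus cliff generators across fingerprint schemes, benchmarks multiclass
    one-vs-rest QSAR classifiers with cross-validation and a PCA bounding-box
    applicability domain, and analyses Murcko-scaffold chemotypes. Ships a synthetic
    inhibitor-library generator with known ground truth (scaffold frequencies, class
    counts, planted activity cliffs) so the whole pipeline is verifiable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    withr,
    MASS,
    e1071,
    randomForest,
    ranger,
    xgboost,
    rpart,
    nnet,
    class,
    glmnet,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
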