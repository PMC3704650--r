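Package: phenologr
Title: Cross-Species Gene-Phenotype Prediction with k-Nearest-Neighbour
    Phenologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies orthologous phenotypes ("phenologs") -- pairs of
    phenotypes in different species whose associated gene sets overlap more
    than expected by chance under gene orthology -- and integrates the k
    nearest neighbour phenotypes of a target phenotype into ranked candidate
    gene predictions, using either an additive or a naive Bayes scoring
    scheme. Provides gene-based and orthogroup-based matrix frameworks for
    translating annotations between species, six set-overlap similarity
    measures including the hypergeometric tail probability, orthogroup-aware
    leave-one-out and n-fold cross-validation with recovery curves and
    ROC/precision-recall summaries, dataset-construction filters for GO
    annotation, phenomic-profile and expression-location data, and a
    synthetic-data generator with planted deep-homology structure for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
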