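Package: cfbench
Title: Benchmarking Composite-Feature Classifiers for Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for outcome classifiers that integrate
    gene-expression data with secondary data sources such as protein-protein
    interaction networks and pathway gene-set collections. Implements four
    feature-extraction methods (single genes, mutual-information subnetwork
    search, condition-responsive gene scoring, hub correlation-difference
    features), three classifiers (nearest-mean, weighted 3-nearest-neighbour,
    ridge-guarded logistic regression), a strictly leakage-free cross-dataset
    evaluation protocol, topology-preserving randomization of secondary data,
    size-corrected signature-stability analysis, and a synthetic multi-cohort
    data generator with planted differential modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
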