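Package: fedgnn
Title: Federated Ensemble Graph Neural Networks on Protein-Protein
    Interaction Networks with Human-in-the-Loop Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Disease classification from gene expression profiles modelled as
    attributed protein-protein interaction (PPI) graphs, one graph per patient.
    A message-passing graph neural network is trained per cohort, a
    gradient-based explainer scores node and edge importance, and connected
    high-importance subgraphs seed an ensemble of small graph classifiers
    combined by weighted majority voting with expert-adjustable weights.
    A coordinator/client protocol is simulated in-process: local ensembles are
    detached from patient data, concatenated into a global federated ensemble,
    and per-member vote weights contributed by several experts are averaged
    elementwise. Includes a synthetic-data generator (scale-free PPI plus a
    planted class-conditional expression signal on a connected subnetwork) so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'graphio.R'
    'gnn.R'
    'explain.R'
    'ensemble.R'
    'federation.R'
    'fedgnn-package.R'
    'synthdata.R'
    'pipeline.R'
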