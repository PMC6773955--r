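Package: DrugSigNet
Title: Signature-Reversal Drug Repositioning with Network Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-step transcriptome-based drug-repositioning pipeline for
    case/control disease cohorts. Step one scores every drug signature in a
    perturbation library against disease differential-expression signatures
    using the Kolmogorov-Smirnov connectivity statistic, normalizes the
    weighted connectivity scores within cell-line strata, converts them to
    signed tau percentiles, and selects reversal candidates by cross-dataset
    consensus. Step two retains only candidates whose targets fall inside a
    protein-protein-interaction disease subnetwork built from consensus
    differentially expressed genes, constructs bounded shortest-path
    mode-of-action networks between drug targets and known disease genes, and
    characterizes them by gene-set over-representation analysis. A rank-based
    drug-set enrichment stage with inverse-variance, Fisher and Tippett
    meta-analysis validates rankings against a reference drug set, and a
    fully seeded synthetic-world generator provides ground-truth data for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
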