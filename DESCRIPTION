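Package: kernelDRP
Title: Kernel-Based Drug Response Prediction from Patient-Derived Cell
    Pharmacogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts effective targeted therapies for cancer patients from
    somatic-mutation profiles using a kernel-based bipartite-graph learning
    model trained on patient-derived-cell (PDC) pharmacogenomics. Builds
    Jaccard kernels over binary mutation profiles and Tanimoto kernels over
    drug chemical fingerprints, represents each (cell, drug) pair by its
    similarities to training anchors, digitalizes continuous dose-response
    AUC into binary sensitivity labels on the cell-drug bipartite graph,
    fits random-forest or RBF support-vector classifiers with seeded
    stratified cross-validation and grid search, and ranks drugs and drug
    mechanism classes per patient. Also provides the accompanying
    descriptive whole-exome summaries (somatic subtraction of germline
    calls, per-chromosome SNP distributions, 12-type substitution spectra,
    per-gene sequencing coverage, ranked driver-list overlap) and a fully
    seeded synthetic-data generator with planted genotype-to-class
    sensitivity rules so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ranger,
    nnet,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr
Config/testthat/edition: 3
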