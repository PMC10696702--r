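Package: metabrisk
Title: Replicated Metabolomics Biomarker Discovery with Network and Genetic Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pre-diagnostic case-control serum
    metabolomics studies: quality-control feature filtering and assay-precision
    reporting, log plus Pareto scaling, from-scratch PCA / PLS-DA / OPLS-DA with
    cross-validated Q2, permutation significance and VIP scores, replicated
    biomarker selection across two independent sets, chemical super-class
    over-representation, Gaussian graphical model partial-correlation networks
    with betweenness centrality and per-metabolite effect z-scores, SNP quality
    control with exact Hardy-Weinberg testing, age-adjusted logistic GWAS,
    weighted-allele genetic risk scores, and logistic ROC/AUC prediction models.
    Includes a synthetic-data generator with known planted effects so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
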