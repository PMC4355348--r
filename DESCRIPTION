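Package: gspanel
Title: Genetic Diversity and Genomic Prediction for Selfing Crop Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of marker diversity and genomic
    prediction in structured, highly selfing crop diversity panels. Covers
    summary statistics for SNP, SSR and RBIP marker systems (PIC, MAF,
    Rogers distances), Mantel tests, complete-linkage clustering, linkage
    disequilibrium decay, DAPC-style population structure inference with
    BIC model selection, empirical-Bayes (ComBat-style) adjustment of
    genotypes for structure, probabilistic-PCA genotype imputation, six
    whole-genome regression methods (LASSO, PLS, sparse PLS, GBLUP, Bayes
    A, Bayes B) behind a single fitting interface, and a repeated
    train/test evaluation protocol (MSEP, R2, Q2). A synthetic-panel
    generator with Balding-Nichols differentiation, founder-haplotype
    linkage disequilibrium and additive traits makes the whole pipeline
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    sva,
    mixOmics,
    vcfR
Config/testthat/edition: 3
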