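Package: mangoGP
Title: Multi-Collection Genomic Prediction, GWAS and Diversity Analysis for
    Clonally Propagated Tree Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating several germplasm collections of a clonal
    tree crop (the motivating case is mango) into a single genomic analysis:
    VanRaden genomic relationship matrices from biallelic SNP dosages, GRM
    principal-component analysis, linkage-disequilibrium decay with an
    unlinked-pair background threshold, an effective-number-of-independent-SNPs
    multiple-testing correction, average-information REML for SNP-based
    heritability and bivariate genetic correlations, a mixed-linear-model
    association scan with polygenic control, and a five-model genomic
    prediction family (single trait, multi-environment, genotype-by-environment,
    multi-trait, and trait-by-genotype interaction) fitted by Bayesian kernel
    regression with Hadamard-product interaction kernels, evaluated under CV1
    and CV2 cross-validation and inter-collection prediction scenarios. A
    mosaic-copying simulator generates multi-collection genotypes and
    phenotypes with controllable admixture, LD decay, heritability, genetic
    correlation, genotype-by-environment variance, and fruit-sampling recording
    protocols for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
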