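Package: tetrags
Title: Genotyping-by-Sequencing Genotype Calling, GWAS and Genomic Selection
    for Autotetraploid Half-Sib Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for quantitative genetics on
    genotyping-by-sequencing (GBS) data from autotetraploid outbreeders
    phenotyped through replicated half-sib progenies. Converts allele
    read counts to depth-filtered diploid-coded genotype matrices with a
    tetraploid miscall-probability calculator, imputes missing calls by
    K-nearest-neighbour imputation, estimates half-sib variance components,
    broad-sense heritability, genetic coefficients of variation, type-B
    genetic correlations and BLUP-adjusted progeny phenotypes, runs a
    single-marker genome-wide association scan with genomic-control
    inflation adjustment and gene-context annotation, and fits five
    genomic-prediction models (ridge-regression BLUP with REML by spectral
    decomposition, Bayes A, Bayes B, Bayesian Lasso via Gibbs sampling, and
    linear support-vector regression) evaluated by repeated k-fold
    cross-validation. A synthetic-data generator with known truth supports
    calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    optparse,
    knitr
Config/testthat/edition: 3
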