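Package: LipidLens
Title: Untargeted Plasma Lipidomics: Trait Association, Lipidome Variance
    Partition, and Rule-Based Phospholipid Annotation
Version: 0.1.0
Authors@R:
    person("Plasma", "Lipidomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for untargeted negative-mode
    plasma lipidomics feature tables. Implements relative-mass-defect and
    missingness filtering, mean imputation, internal-standard normalization
    and Pareto scaling; age- and smoking-adjusted single-lipid regressions
    with Benjamini-Hochberg and Bonferroni multiplicity control; sample
    cross-product principal component analysis and an SVD biplot of the
    lipid-by-trait effect matrix; a Bayesian kernel (RKHS/GBLUP-style)
    variance-partition model fit by a Gibbs sampler that reports the
    fraction of trait variance attributable to the whole lipidome; and a
    rule-based MS/MS annotation engine for glycerophospholipids built on
    exact monoisotopic mass arithmetic. A synthetic-data module generates
    cohorts, feature tables, traits and spectra with known ground truth so
    the whole pipeline is testable without access to cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
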