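Package: METimpute
Title: Multiple Imputation for Three-Way Multi-Environment Trial Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputation of missing cells and wholly missing environment-attribute
    columns in three-way three-mode multi-environment trial (MET) arrays of
    genotypes x environments x attributes. Implements multiple agglomerative
    hierarchical clustering imputation (MAHC) over random attribute subsets,
    normal distribution model (NORM) and normal regression model (NRM)
    imputation with maximum-likelihood or conjugate Gibbs (Bayesian)
    estimation, predictive mean matching (PMM) with bootstrap refitting, and
    an EM/Tucker3 single-imputation baseline. Includes Rubin's-rules pooling
    with confidence-interval coverage evaluation, NRMSE benchmarking, a
    variance-components simulator for fixture MET arrays, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
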