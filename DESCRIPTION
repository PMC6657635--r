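Package: multicmdr
Title: Multivariate Cluster-Based Multifactor Dimensionality Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects gene-gene interactions (epistasis) for multiple
    correlated quantitative phenotypes with a cluster-based multifactor
    dimensionality reduction (multi-CMDR) procedure. Samples are
    partitioned by fuzzy c-means clustering with an additional noise
    cluster that absorbs outliers; multilocus genotype cells are labeled
    by comparing per-cell membership-mass ratios against a global ratio;
    candidate SNP sets are ranked by Hotelling's T-squared statistics
    under N-fold cross-validation with cross-validation consistency, and
    significance is assessed by permutation. Includes the univariate QMDR
    and first-principal-component multi-QMDR comparison methods, plus a
    simulation toolkit generating Hardy-Weinberg genotypes and bivariate
    normal or Gaussian-copula bivariate gamma phenotypes driven by 3x3
    penetrance tables.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
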