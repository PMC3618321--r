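Package: pathvar
Title: Single-Sample Gene-Set Variation Scoring and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Non-parametric, unsupervised estimation of per-sample pathway
    activity from expression data. Implements gene set variation analysis
    (kernel cumulative-density expression statistics with Gaussian or
    Poisson kernels, symmetric rank statistics and a Kolmogorov-Smirnov-like
    weighted random walk yielding maximum-deviation or two-tail-difference
    enrichment scores) together with three comparator single-sample methods
    (PLAGE, combined z-score, ssGSEA), GMT/TSV input-output, a linear
    additive simulation model of two-group expression experiments, and
    benchmark harnesses estimating statistical power, empirical type-I
    error and differential-pathway-calling AUC, plus survival-time
    generation for predictive scoring studies. Includes Hartigan's dip
    statistic with a Monte-Carlo unimodality test used to characterise
    null score distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pROC,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
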