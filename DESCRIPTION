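Package: dapower
Title: Taxon-Level Power Analysis for Differential Abundance Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates realistic case-control microbiome count data and
    estimates taxon-by-taxon statistical power for negative binomial
    differential abundance tests. A pilot count table is summarised into a
    generative community model: a finite Gaussian mixture for log mean
    abundance (order chosen by parametric-bootstrap likelihood-ratio
    tests), a conditional Gaussian mixture for log fold change with
    abundance-dependent means and variances (order and variance form
    chosen by AIC), and a reciprocal dispersion-mean trend. Synthetic
    cohorts drawn from the model are pushed through a self-contained
    negative binomial Wald pipeline (median-of-ratios normalisation,
    per-taxon dispersion maximum likelihood, empirical-Bayes fold-change
    shrinkage, Benjamini-Hochberg correction), and per-taxon detection
    outcomes are smoothed with a shape-constrained Bernoulli model whose
    tensor-product surface is monotone in both log mean abundance and
    absolute log fold change. Summaries include per-taxon power, average
    power, and the expected number of significant taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
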