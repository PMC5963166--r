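Package: lerouxmap
Title: Bayesian Disease Mapping with the Leroux Conditional Autoregressive Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area analysis of standardized mortality ratios with a
    hierarchical Bayesian Poisson regression carrying a Leroux conditional
    autoregressive (CAR) spatial random effect. Provides indirect
    standardization over sex-by-age strata, Moran's I permutation tests of
    spatial autocorrelation on binary contiguity graphs, variance-inflation
    screening of covariates, a Metropolis-within-Gibbs sampler for the
    Leroux model with Geweke convergence diagnostics and WAIC model
    comparison against a non-spatial Poisson baseline, a synthetic-data
    generator for region-level stratified count data, and an end-to-end
    pipeline producing publication-shaped summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    coda,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
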