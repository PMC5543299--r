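Package: sirscan
Title: Small-Area Disease Mapping with Bayesian Smoothing and Spatial Scan
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area analysis of disease incidence counts:
    internally standardized incidence ratios (SIR), Moran's I permutation
    tests, Marshall-type spatial empirical Bayes smoothing over contiguity
    neighbourhoods, the Besag-York-Mollie (BYM) convolution model fitted by
    Metropolis-within-Gibbs with intrinsic CAR spatial effects and
    Brooks-Gelman-Rubin diagnostics, and a purely spatial Poisson scan
    statistic with circular windows, Monte Carlo inference and Gini-based
    selection of the maximum cluster size. A synthetic-data generator
    produces lattices, heterogeneous populations and spatially
    autocorrelated risks with implanted clusters so the whole pipeline is
    testable without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
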