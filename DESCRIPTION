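Package: edgescreen
Title: Model-Free Feature Screening with Graph-Based Edge-Count Tests and
    Dependence-Adjusted FDR Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step model-free screening of continuous features against a
    categorical outcome. Each feature is tested for equality of the J
    conditional distributions with a k-MST edge-count test (a quadratic
    statistic on within-group edge counts of a union of k edge-disjoint
    Euclidean minimum spanning trees, asymptotically chi-squared with J
    degrees of freedom, with a permutation fallback for small groups).
    Features are then selected by Efron's dependence-adjusted empirical-null
    procedure, which estimates a dispersion statistic from the central mass
    of the z-values and inflates the rejection threshold to keep the false
    discovery rate controlled under correlated tests; Benjamini-Hochberg is
    provided as a comparator, as are Welch's unequal-variance t test and a
    mutual-information z test. Includes a simulation suite that reproduces
    the power/FDR benchmark designs the method was validated on, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
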