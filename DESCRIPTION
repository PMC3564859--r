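Package: smets
Title: Semi-Metric Comparison of Multivariate Time Series of Unequal Dimension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes SMETS (Semi Metric Ensemble Time Series), a semi-metric
    distance between multivariate time series that may have different numbers
    of component variables. Components of the lower-dimensional series are
    greedily matched to their most similar counterparts in the other series,
    matched distances are aggregated with a p-norm (p equal to the smaller
    dimension), and unmatched components are penalized through their Shannon
    entropy together with a dimension-ratio penalty. Univariate component
    distances are Euclidean distances between truncated largest-magnitude
    Haar discrete wavelet transform representations, which lower-bound the
    raw Euclidean distance. Includes z-normalization and zero-padding
    preprocessing, pairwise distance matrices with agglomerative hierarchical
    clustering (Newick export), a weighted-average baseline comparator, a
    synthetic toy-model generator (oscillators, relaxations, constant traces,
    random walks), and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
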