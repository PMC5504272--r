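Package: statescape
Title: Energy-Landscape Analysis of Binarized Brain-Network Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits pairwise maximum-entropy (Ising) models to binarized
    multivariate activity time series, builds the exhaustive energy landscape
    over all activity patterns, and characterizes dynamics as stays in and
    transitions between major and minor brain states (local minima, basins of
    attraction, disconnectivity graphs, Metropolis-Hastings random walks).
    Includes network-level functional-connectivity segregation statistics,
    permutation-based group inference, diagnosis prediction from dynamics
    indices, and a synthetic-cohort generator with planted group contrasts and
    behavioural associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    car,
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
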