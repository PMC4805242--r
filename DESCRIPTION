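Package: flowEMD
Title: Earth Mover's Distance for Comparing Flow Cytometry Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies differences between biomarker-expression
    distributions of cell populations with the Earth Mover's Distance
    (EMD), a true metric on probability distributions. Samples are
    summarized as probability-binning signatures (recursive median splits
    along the maximum-variance channel), and EMD is computed by solving
    the transportation linear program with Euclidean ground distances
    between bin centroids. Includes baseline comparison measures
    (probability-binning statistic, chi-square, Mahalanobis distance,
    median fluorescence intensity deltas), a linear support-vector-machine
    classification workflow with repeated sub-sampling validation, readers
    for FCS and delimited event tables with asinh and Logicle transforms
    and rectangular gating, and generators for synthetic
    flow-cytometry-like cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
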