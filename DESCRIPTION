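Package: izhifit
Title: Fitting and Classifying Quadratic Spiking-Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation of the two-variable Izhikevich spiking-neuron model
    with after-spike reset, analytic fixed-point analysis, rule-based
    classification of canonical firing patterns, spike sorting of synthetic
    extracellular recordings (band-pass filtering, threshold detection,
    PCA features, k-means clustering, interspike-interval and correlogram
    validation), and recovery of the model's four parameters from target
    membrane-potential traces with a real-coded genetic algorithm
    minimizing mean-square voltage error.  All pipeline inputs can be
    generated synthetically with known ground truth, making parameter
    recovery and sorter accuracy measurable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
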