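Package: ephyslink
Title: Biophysical Neuron Models, Robust Simulation-Based Inference, and
    Gene-Expression Linkage for Patch-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid statistical-biophysical pipeline for Patch-seq cohorts.
    Simulates a 13-parameter single-compartment Hodgkin-Huxley-type neuron
    under a step-current protocol, extracts 23 electrophysiological summary
    features, fits the biophysical parameters by neural posterior estimation
    with a misspecification-robust noise-augmented training schedule (NPE-N),
    and links the fitted parameters to gene expression with rank-2 sparse
    reduced-rank regression. Includes a synthetic Patch-seq cohort generator
    coupling ground-truth biophysics to negative-binomial gene counts so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
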