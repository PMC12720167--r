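Package: fpsmap
Title: Prospective E-Field-Informed TMS Motor Mapping with Farthest Point
    Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for prospective, electric-field-informed transcranial
    magnetic stimulation (TMS) motor mapping. Implements greedy farthest
    point sampling of coil configurations by dissimilarity of their induced
    field-magnitude maps over a cortical region of interest, a synthetic
    motor-evoked-potential (MEP) generation model on folded cortical patch
    geometry, per-compartment sigmoid input-output fitting into R-squared
    motor maps, normalized map-overlap scoring, EMG trial preprocessing
    rules, and end-to-end sample-efficiency benchmarking of sampling
    protocols against a random-sampling baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
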