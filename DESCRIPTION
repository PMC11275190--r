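Package: protospike
Title: Spike-Train, Harmonic and Complexity Analysis of Proteinoid
    Microsphere Electrical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for electrical recordings of proteinoid
    (thermal protein) microsphere ensembles under graded chloroform
    exposure.  Provides a calibrated synthetic-data generator for voltage
    and chronoamperometric current traces, B-spline baseline detrending,
    spike detection and moment statistics (amplitude and interspike
    interval), dose-response attenuation summaries, least-squares harmonic
    decomposition, a neuromorphic binary-coding and random synaptic-weight
    abstraction, Lempel-Ziv (LZ76) complexity, and an energy-decomposition
    audit for molecular-mechanics ledgers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    splines,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
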