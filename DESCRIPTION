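Package: graspdyn
Title: Grip-Type and Grasp-Force Coding in Neural Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying grip-type and grasp-force coding in neural
    population recordings from a delayed grasping task. Implements trial
    behavior metrics with exclusion rules, continuous-signal conditioning
    (Gaussian smoothing, EMG band-pass/rectify/normalize, median high-pass,
    PCA artifact cancellation), peristimulus time histograms on a three-
    alignment composite timeline, cluster-based permutation tests of firing
    rate tuning, demixed principal component analysis with decoding-based
    significance, EMG marginalizations, and time-shifted neural-muscle
    correlation. A synthetic-session generator with planted latent structure
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
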