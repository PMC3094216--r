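Package: seizhmm
Title: Unsupervised Multistage Seizure Dynamics Detection with
    Wavelet-Feature Gaussian-Mixture Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects the multistage progression of seizure-like events
    (interictal, early and late tonic firing, chronic seizure, postictal)
    in single-channel local field potential recordings without supervised
    labelling.  Features are mean-magnitude Morlet continuous-wavelet
    coefficients over seven physiological frequency bands computed on
    non-overlapping one-second windows, optionally augmented with their
    rate of change.  A hidden Markov model with mixture-of-Gaussians
    emissions is trained by Baum-Welch expectation-maximization; the
    feature space is reduced by minimum-redundancy maximum-relevance
    ranking and the topology (number of states and clusters) is chosen by
    the corrected Akaike information criterion.  Trained states are mapped
    to electrographic stages by an expert-guided assignment anchored on a
    chronic interval marked either from annotations or a short-time
    maximum Lyapunov exponent trace, and detector performance is reported
    as sensitivity, specificity, detection delay and an optimality index.
    A synthetic seizure-like signal generator with ground-truth stage
    labels is included for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
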