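Package: condbench
Type: Package
Title: Diagnostic Classical-Conditioning Benchmarks for Online Prediction Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Seeded discrete-time simulators for three diagnostic prediction
    benchmarks inspired by animal-learning experiments -- trace conditioning,
    noisy patterning, and trace patterning -- together with a suite of online
    learners: semi-gradient TD(lambda) over fixed temporal representations
    (presence, stimulating traces, tile-coded traces, microstimulus, echo
    state networks) and recurrent networks (vanilla RNN, LSTM, GRU) trained
    fully online by truncated backpropagation through time or real-time
    recurrent learning, with an optional stimulating-trace input
    augmentation. Performance is evaluated as mean squared return error
    against retrospectively computed discounted-return targets, with seeded
    multi-run aggregation, parameter sweeps, and trial-aligned prediction
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
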