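Package: respigate
Title: Respiratory-Signal Prediction and Gating-Error Feasibility for Latency-Compensated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates respiration surrogate traces with controlled period and
    amplitude irregularity, quantifies breathing irregularity from peak/valley
    statistics, and trains three small sequence forecasters (a stacked LSTM, a
    bidirectional LSTM, and an encoder-decoder Transformer) to predict the
    respiratory signal a machine-latency ahead of the input window. Prediction
    error is translated into millimetre gating error at the 30% and 70%
    respiratory phases under an assumed tumor excursion, the quantity that
    decides whether a beam-control latency is clinically tolerable for gated
    radiotherapy. The neural networks and their Adam training loop are
    implemented natively (RcppArmadillo) so the pipeline has no deep-learning
    framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
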