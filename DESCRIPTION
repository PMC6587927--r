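Package: p300decode
Title: Cross-Experiment P300 Decoding with a Compact Convolutional Network
Version: 0.1.0
Authors@R: person("p300decode", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, decoding and statistical analysis of
    the P300 event-related potential across heterogeneous EEG experiments.
    Provides a synthetic multi-experiment EEG generator (1/f background,
    alpha-band oscillation, parietal-maximal evoked component with
    condition-dependent amplitude and latency), the standard conditioning
    pipeline (zero-phase bandpass, resampling to 128 Hz, median-absolute-
    deviation normalization, epoching), a compact convolutional decoder with
    depthwise and separable convolutions trained with class- and
    experiment-balancing sample weights under a leave-one-experiment-out
    scheme, sliding-window decoding that yields per-trial probability traces,
    and the ROI amplitude / window-mean / trial-downselection statistics used
    to compare decoder-based and amplitude-based condition contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
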