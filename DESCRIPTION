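Package: gcnet
Title: Sliding-Window Spectral Granger Causality Networks for Source-Level EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of directed frontoparietal brain networks
    from source-level EEG during multi-phase cognitive tasks. Generates
    cohorts of trials from time-varying stable vector autoregressive (VAR)
    processes with band-specific coupled oscillators, reproduces a
    conditioning protocol (1-60 Hz zero-phase bandpass, baseline correction,
    per-window detrending, ADF/KPSS stationarity gating with first-order
    differencing), computes frequency-domain (Geweke) Granger causality per
    nonoverlapping 100-ms window with BIC-selected VAR order, builds
    baseline-referenced binary directed networks by cluster-based permutation
    testing, and summarises them with causal density, characteristic path
    length, causal flow, and per-window group ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
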