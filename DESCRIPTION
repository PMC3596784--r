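Package: finitenet
Title: Simulation and Analysis of Finite-Size Spiking Neuronal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating spontaneously bursting finite-size
    neuronal networks (heterogeneous regular-spiking and fast-spiking
    Izhikevich neurons, Ornstein-Uhlenbeck noise currents, pulse coupling
    on scale-free directed graphs) and for the analysis chain applied to
    such circuits: calcium fluorescence event detection with sigmoidal
    onset/offset estimation, directed functional connectivity inference
    from event-onset series, time-lagged cross-correlation summaries,
    network-event rate statistics, peri-stimulus time histograms and
    evoked-spike counts, and a stationary-wavelet-transform spike
    detector with an optional fixed-point mode. A synthetic-data module
    generates ground-truthed fluorescence recordings, onset series and
    extracellular traces so that every analysis stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
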