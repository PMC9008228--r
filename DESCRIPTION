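Package: hdseizure
Title: Multi-Centroid Hyperdimensional Computing for EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary hyperdimensional (HD) computing classifier for epileptic
    seizure detection from multichannel EEG. Windows of EEG are summarised by
    entropy, band-power and amplitude features, discretised, and encoded into
    10,000-bit hypervectors with XOR binding against channel-feature and
    value-level codebooks and majority-vote bundling. Training is single-pass
    and multi-centroid: a sub-class prototype is spawned whenever a training
    window is nearest to a wrong-label prototype, capturing distinct seizure
    and background sub-types without fixing their number in advance. Two
    post-hoc sub-class reduction procedures (removal and clustering of the
    least-populated sub-classes) shrink the model under a train-performance
    tolerance. Includes episode- and duration-level detection metrics with
    majority-vote label smoothing, leave-one-seizure-out cross-validation
    under balanced and unbalanced (1x/5x/10x interictal) dataset regimes,
    EDF input, and a sub-typed synthetic EEG generator for end-to-end
    benchmarking without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
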