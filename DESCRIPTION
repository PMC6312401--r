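Package: encodeEEG
Title: Forward (Inverted) Encoding of Orientation Selectivity in EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing feature-selective neural responses
    from multichannel EEG with forward (inverted) encoding models.
    Implements the half-cosine basis set over orientation space,
    cross-validated least-squares weight estimation and inversion on a
    sliding time window, response centering, Gaussian tuning-curve
    quantification, diagonal naive Bayes backward decoding,
    cross-temporal generalisation, and group-level sign-flip permutation
    statistics with cluster-mass correction. A forward simulator
    generates factorial repetition/expectation session designs and
    sensor-level epochs with known, recoverable orientation tuning, so
    the full pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
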