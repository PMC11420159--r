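Package: earqc
Title: Signal-Quality Evaluation of Dual In-Ear and Scalp EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking a single-channel in-ear EEG device
    against a multichannel scalp EEG system recorded simultaneously.
    Implements trigger-based synchronization of two independently clocked
    acquisition systems, anti-aliased resampling and zero-phase FIR
    band-limiting, amplitude-threshold artifact rejection on 10-s epochs,
    RMS and bad-data summaries, Gabor-wavelet spectrograms with an
    alpha-band signal-to-noise statistic, relative spectral power in
    canonical bands per sleep stage, lag-tolerant cross-correlation against
    contralateral bipolar scalp derivations, and block-permutation
    inference with Benjamini-Hochberg FDR control. A synthetic
    paired-recording generator reproduces the eyes-open/eyes-closed alpha
    protocol and stage-structured nap recordings so the full pipeline is
    testable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
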