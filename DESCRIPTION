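Package: seqspectrum
Title: Sequential Spectrum Analysis of Nonstationary Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symbolic characterization of one-dimensional signals by the
    sequential spectrum (seq-spectrum). The first differences of a sampled
    signal are encoded as binary symbols (1 for non-decreasing, 0 for
    decreasing steps), maximal single-symbol runs (mono-sequences) are
    counted, and their length-resolved relative contribution (binary
    occupancy) forms a spectrum-like descriptor that remains meaningful for
    nonstationary series such as EEG. Includes relative spectra between
    conditions, a symbol-0/symbol-1 congruity index, windowed
    seq-spectrograms, a suite of reference signal generators (colored noise
    with prescribed fluctuation exponent, linear chirps, harmonic sums with
    graded noise contamination, random-section removal, logistic-map
    trajectories), a detrended fluctuation analysis estimator, basic
    CSV/text/EDF input, TSV/JSON output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
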