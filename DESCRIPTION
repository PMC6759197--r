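Package: locorhythm
Title: Analysis of Fictive Locomotor Rhythms in Spinal Cord Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies optogenetic perturbation of locomotor-like rhythms
    recorded from the isolated neonatal rodent spinal cord. Provides
    neurogram integration (zero-phase Butterworth cascade), complex-Morlet
    wavelet spectrograms with ridge frequency and cross-wavelet phase time
    series, burst segmentation at a fractional trough-to-peak threshold with
    duty-cycle and interburst metrics, pointwise bootstrap t tests with
    banded significance, circular statistics (Rayleigh, Watson-Williams,
    Harrison-Kanji), cycle-triggered analysis of intracellular drive
    potentials, calcium-imaging trace conditioning (doughnut neuropil
    subtraction, monoexponential bleach correction, dF/F, band-pass), and a
    seeded synthetic-data generator that emulates the recordings with known
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    minpack.lm,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
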