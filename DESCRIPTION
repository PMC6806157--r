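Package: patchfreq
Title: Frequency-Domain Features and Tree Classifiers for Nanoparticle Sensor Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies small grayscale image patches from surface plasmon
    resonance (SPR) nanoparticle sensors as containing a particle binding or
    not. Extracts ten Fourier spectral texture features (radial and angular
    magnitude-spectrum profiles with summary statistics) and ten Haar wavelet
    subband energy features from 32x32 patches, trains depth-limited decision
    trees and bagged forests on them, ranks features by PCA explained
    variance, plans reduced extraction pipelines for selected feature
    subsets, and exports trained trees as deployable if-else source code.
    Includes a seeded generator of synthetic positive (blob plus decaying
    ring) and negative (noise, vibration, streak) patches so the full
    pipeline is testable without sensor data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tiff
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
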