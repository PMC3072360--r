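Package: morphodyn
Title: Order-Parameter Analysis of Single-Cell Shape Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the spontaneous shape dynamics of single cells imaged
    as time-lapse binary silhouettes. Computes the relative radial roundness
    order parameter R(t) from perimeter and area pixel counts, a battery of
    nonlinear time-series measures on R(t) (central moments, Wolf leading
    Lyapunov exponent, log-log power-spectral scaling exponent, slowest
    Fourier-mode period), phase-space representations (Broomhead-King
    eigenfunction embedding, recurrence plots) and Morlet continuous-wavelet
    scalograms with a change-point summary for behavioral state transitions.
    Includes a seeded generator of synthetic silhouette movies emulating
    idling, treadmilling and translocating neutrophil shape states, and a
    pooled-variance two-group comparison of per-cell measure sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
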