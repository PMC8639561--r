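Package: ddmsf
Title: Image Structure Functions for Differential Dynamic Microscopy and
    Dynamic Shadowgraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the image structure function d(q, m*dt) of a grayscale
    image time series, the central observable of differential dynamic
    microscopy (DDM) and dynamic shadowgraphy. Provides a literal
    difference-then-transform reference engine, a cached-spectra engine that
    differences spatial Fourier transforms, and an accelerated engine that
    evaluates the lag correlation of each wave vector's time series through
    the Wiener-Khinchin theorem (temporal FFT of zero-padded series),
    reducing the per-wave-vector cost from O(N^2) to O(N log N). Includes
    memory-budgeted chunked execution, azimuthal averaging onto wave-number
    rings, single-exponential intermediate-scattering-function fits yielding
    decay times tau(q), a diffusive-scaling fit for the diffusion
    coefficient D, and a synthetic Brownian-motion image generator with
    analytically known dynamics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    tools,
    tibble,
    ggplot2,
    generics,
    minpack.lm,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
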