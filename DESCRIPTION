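Package: dnafluct
Title: Viscoelasticity of Single DNA Molecules from Long-Axis Fluctuation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the effective spring constant and damping constant of
    single giant DNA molecules from thermal fluctuations of their apparent
    long-axis length, following the fluctuation-dissipation framework: the
    stationary autocovariance of the length time series is fitted with a
    damped cosine, the spring constant is obtained from the zero-lag
    variance via k = kBT/C(0), and the damping constant and angular
    frequency from the fitted envelope and oscillation. Ships a
    stationary-Gaussian-process and an exact underdamped-Langevin simulator
    with known ground truth, a fluorescence-microscopy-style image-stack
    renderer and a segmentation-based length extractor, closed-form
    semiflexible-polymer and counterion-condensation reference theory, and
    an end-to-end reproducible pipeline with per-condition summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
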