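Package: qmixture
Title: Simulation and Analysis of Interleaved Prepared Turbo Spin-Echo Relaxometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and evaluation toolkit for combined
    morphologic and quantitative knee MRI based on interleaved,
    magnetization-prepared turbo spin-echo (TSE) acquisitions. Builds
    synthetic knee phantoms with depth-dependent cartilage relaxation,
    simulates steady-state magnitude images with Rician noise for
    T2-prepared and spin-lock-prepared sequence variants and their 2D/3D
    TSE references, reconstructs voxel-wise T2 and T1rho maps by
    mono-exponential fitting with validity masking, computes ROI-based
    Weber contrast, contrast-to-noise ratio and coefficient of variation,
    and provides the reader-study statistics: paired sample-size
    estimation, ordinal Likert-score simulation, cumulative link mixed
    models fitted by the Laplace approximation with latent-scale
    estimated marginal means and Tukey-adjusted contrasts, and
    repeated-measures ANOVA with Tukey-Kramer post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
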