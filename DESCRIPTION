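Package: petrad
Title: PET Radiomic Feature Stability with Adaptive Threshold Segmentation
    and Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement chain for PET radiomic feature stability studies:
    contrast-oriented adaptive threshold tumor segmentation, fixed-bound
    absolute intensity discretization, and extraction of eight conventional,
    histogram and textural features (SUVmean, tumor-to-muscle ratio, skewness,
    kurtosis, GLCM entropy and homogeneity, GLRLM short- and long-run
    emphasis) from 3-D SUV volumes. Includes a paired-scanner phantom
    simulator emulating early and delayed acquisitions with
    attenuation-correction bias, duration-dependent noise, Gaussian
    post-smoothing and voxel-grid resampling, and the repeated-measures
    comparison statistics (Pearson correlation, one-way RM-ANOVA, paired
    post-hoc tests, percent differences) needed for cross-scanner stability
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
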