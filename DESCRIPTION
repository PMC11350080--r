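Package: stemspec
Title: Chemometric Analysis of FTIR Spectra and Hyperspectral Images of
    Plant Stem Tissue
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies cell-wall components in Fourier-transform infrared
    (FTIR) spectra of plant stems with an extended multiplicative signal
    correction (EMSC) decomposition, segments hyperspectral FTIR images of
    stem cross-sections into functional tissue clusters by hierarchical
    clustering of fingerprint spectra, compares tissue-cluster chemistry
    between genotypes with Mann-Whitney tests and divergence effect sizes,
    and screens bulk ATR-FTIR compound signatures against adventitious
    rooting traits (relative-percent-difference filter plus trait
    correlations). Includes ENVI and CSV spectral I/O and a fully seeded
    synthetic-data generator that emulates stem-section geometry, mixture
    spectra, scatter/baseline distortions and genotype panels with planted
    effects and exported ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
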