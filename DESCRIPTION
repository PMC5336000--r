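Package: fuseval
Title: Pansharpening Algorithms and Quality Evaluation for Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fusing low-resolution multispectral imagery with a
    high-resolution panchromatic band (pansharpening) and for assessing the
    quality of the fused products. Implements four fusion algorithms --
    fast intensity-hue-saturation substitution, hyperspherical colour
    sharpening, MTF-matched generalized Laplacian pyramid with high-pass
    modulation, and weighted wavelet 'a trous' fusion driven by fractal
    dimension maps -- together with six reference-based quality indices
    (spectral angle mapper, spectral and spatial ERGAS, blockwise-DCT
    frequency comparison, Zhou high-pass correlation, and the universal
    image quality index Q), band-subset and block-level quality analysis,
    and Borda-count rank aggregation of algorithms into spectral, spatial
    and global rankings. A synthetic scene generator produces seeded
    multispectral/panchromatic pairs emulating shrubland, coastal and
    mixed land/water ecosystems so the full pipeline can be exercised and
    tested without commercial satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    grDevices,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
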