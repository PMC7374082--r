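Package: chromix
Title: Spectral Unmixing and Optical Characterization for Brightfield
    Multiplex Immunohistochemistry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational pipeline for multispectral brightfield multiplex
    immunohistochemistry with narrow-band chromogens. Converts per-channel
    monochrome image stacks to transmission and absorbance (optical density)
    with blank-field correction, calibrates normalized extinction-coefficient
    matrices from single-stain images, solves per-pixel non-negative least
    squares to unmix chromogen abundances, and renders brightfield- and
    fluorescence-like pseudo-color composites. Includes a synthetic phantom
    generator (Beer-Lambert forward model with illumination vignetting,
    Poisson noise and quantization) and optical-system characterization:
    auto-exposure tuning, flat-field root-mean-square deviation, and
    slanted-knife-edge MTF/resolution estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
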