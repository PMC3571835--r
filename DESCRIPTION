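Package: hyperseed
Title: Hyperspectral Image Chemometrics for Seed Variety Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discriminating seed varieties from visible/near-infrared
    hyperspectral image cubes. Reads and writes ENVI hypercubes, performs
    white/black reference reflectance calibration and spectral cropping,
    extracts square regions of interest, computes mean-spectrum features by
    principal component analysis (PCA) and radial-basis-function kernel PCA,
    selects effective wavelengths at the extrema of image-PCA loadings,
    derives gray-level co-occurrence matrix (GLCM) texture features at the
    selected bands, and trains multiclass least-squares support vector
    machines (grid-searched by cross-validated RMSE) and momentum
    back-propagation neural networks on four spectral/textural feature
    combinations. Includes a seeded synthetic hypercube generator emulating a
    six-variety maize seed study so the full pipeline runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    yaml
Config/testthat/edition: 3
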