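Package: hypernitro
Title: Hyperspectral Chemometrics for Mapping Plant Nitrogen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating total nitrogen content of plant tissue
    from Vis/NIR hyperspectral images. Provides ENVI-format cube input and
    output, white/dark reflectance calibration, region-of-interest spectrum
    extraction, SPXY calibration/prediction partitioning, Random-frog
    wavelength selection with an embedded partial least squares submodel,
    PLSR calibration with leave-one-out cross-validation, and pixel-wise
    chemical imaging of predicted nitrogen. A seed-reproducible synthetic
    scene generator emulates leaf, stem and root samples with
    nitrogen-dependent absorption features so the full pipeline can be
    exercised and tested without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
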