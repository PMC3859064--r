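Package: hsimoist
Title: VIS/NIR Hyperspectral Imaging Chemometrics for Moisture Mapping in Cooked Meat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting and visualizing moisture content in
    muscle tissue from VIS/NIR (400-1000 nm) hyperspectral reflectance images.
    Provides ENVI hypercube input/output, white/dark reflectance calibration,
    band-difference background segmentation, the standard spectral
    pre-treatments (mean/max/range normalization, SNV, MSC, Savitzky-Golay
    derivatives), NIPALS partial least squares regression with leave-one-out
    cross-validated latent-variable selection, pixel-wise chemical-image
    generation, oven-drying moisture reference handling, and a synthetic
    hypercube generator that emulates a cooked chicken-breast study design
    (three cooking temperatures, 72 samples) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
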