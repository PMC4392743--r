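Package: phenocf
Title: Chlorophyll Fluorescence Image Phenotyping Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exploration pipeline for large chlorophyll-fluorescence (CF)
    imaging datasets from pulse-amplitude induction protocols. Encodes a
    55-measure transient protocol (13 CF parameter families), computes
    quantum-yield and quenching parameter images (Fv/Fm, F'v/F'm, NPQ, qP,
    qL, Qy, RFD) pixel-wise from measured fluorescence captures, builds
    contact-sheet overviews, compares treatment groups by whole-image global
    values with Mann-Whitney U tests and radial/box summaries, and clusters
    plants from Bhattacharyya/Hellinger histogram distances with six
    agglomeration methods. A bundled simulator generates FluorCam-like
    synthetic studies with known ground truth so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
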