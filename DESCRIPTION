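Package: mpscreen
Title: Semi-Automated Fluorescence Screening of Microplastic Particles on Filter Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening plastic-suspect particles in Nile-red-stained
    filter scans from digested seafood and similar matrices. Provides
    reproducible segmentation of fluorescence micrographs (global Otsu
    thresholding, morphological cleanup, 8-connected particle labelling),
    per-particle morphometry (Feret diameter, fitted-ellipse axes,
    circularity) and fluorescence features (total particle brightness, RGB
    colour fractions), rule-based classification into microplastic-suspect
    and natural-origin particles, size-class quantification, 2D-to-3D volume
    and mass estimation, and procedural-blank correction with per-category
    limits of quantification. A seeded synthetic stained-filter image
    generator with ground-truth sidecars supports fully offline validation
    of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    igraph,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
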