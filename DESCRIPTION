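Package: serialreg
Title: Two-Stage Rigid Registration and Localised IHC Scoring for Serial
    Histology Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers whole-slide images of serial histology sections in two
    stages: a fast approximate rigid alignment obtained by matching curvature
    maxima of the tissue sections' external boundaries in a Curvature Scale
    Space representation, followed by a distance-gated rigid Coherent Point
    Drift refinement on detected tissue features (fat pockets and nuclei
    clusters) with an optional phase-correlation translation correction.
    Includes entropy-based tissue segmentation with an LBP/SVM artefact
    classifier, Chamfer-distance evaluation of boundary alignment, a localized
    multi-IHC Allred (ER/PR) scoring protocol over registered regions of
    interest, and a deterministic synthetic-section generator used as the test
    substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
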