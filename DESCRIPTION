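Package: mfihc
Title: Tumor-Cell-Restricted Prognosis Marker Scoring for Multiplex
    Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automated prognosis-marker assessment in breast cancer
    from multiplex fluorescence immunohistochemistry (mfIHC) cell tables.
    Malignant epithelial cells are separated from benign glands by combining a
    25 micrometre nearest-myoepithelial-cell distance rule with a rule-based
    gland-level classifier, marker expression is quantified on malignant cells
    only via the mfIHC score (min-max scaled positive-cell fraction plus
    positive-cell mean intensity), five hormone/immune markers are combined
    into a 0-5 prognosis score, and the downstream statistics (Kaplan-Meier,
    log-rank, Cox proportional hazards, time-dependent AUC, chi-square
    association, Spearman correlation, hierarchical clustering) are provided.
    A seeded synthetic tissue-microarray generator with full ground truth, and
    an optional raster front-end (rendering plus watershed re-segmentation),
    make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
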