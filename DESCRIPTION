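Package: riceHRY
Title: Touching-Grain Separation and Head Rice Yield from Bulk Rice Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures head rice yield from top-down images of bulk milled
    rice on a dark conveyor background. Touching kernels are separated by
    detecting concave points on component boundaries with the edge center
    mode proportion (ECMP) score, pairing them under collaborative wedge
    constraints, and cutting along matched pairs. Kernel length is measured
    by a minimum-enclosing-rectangle rotation search (with maximum-distance
    and centroid-rotation comparators), kernels are classified head versus
    broken at the three-quarters reference-length rule, and head rice yield
    is reported as the head-to-total pixel-area ratio. A ground-truthed
    synthetic scene generator emulating japonica- and indica-like kernels
    supports end-to-end validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'preprocess.R'
    'concavity.R'
    'io.R'
    'matching.R'
    'metrics.R'
    'pipeline.R'
    'synthetic.R'
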