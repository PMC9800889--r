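Package: echostrain
Title: Automatic Myocardial Strain Analysis for Echocardiogram Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automatic pipeline for measuring left-ventricular global and
    regional longitudinal strain from grayscale echocardiogram-like video
    sequences. Provides a 3D (2D+time) encoder-decoder segmentation network for
    the myocardium, a RAFT-style optical-flow motion estimator built on an
    all-pairs correlation pyramid with a recurrent update operator, centerline
    extraction and flow-based tracking, arc-length strain computation with
    16-segment regional reporting, and method-agreement statistics
    (Bland-Altman, intraclass correlation). Includes a synthetic
    deforming-ventricle phantom with analytically known masks, point tracks,
    dense displacement fields and strain for validation and tiny-scale network
    training, plus readers and writers for multi-frame TIFF, Middlebury .flo
    flow files and point-track CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
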