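Package: pabscope
Title: Morphometry, Traction Force, and Single-Cell Mechanics Analytics
    for Peripheral Actin Band Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification toolkit for fibroblast cytoskeletal phenotyping:
    segmentation and shape morphometry of phalloidin-stained cells with a
    peripheral-actin-band (PAB) classifier based on border actin fraction and
    circularity; migration-track statistics (speed, directionality,
    wind-rose); calcium fold-change traces; regularized Fourier-transform
    traction cytometry (FTTC) on an elastic half-space with strain-energy
    readout and residual-energy quality control; and Hertzian spherical-
    indenter fitting of AFM force curves. Includes synthetic phantom
    generators with known ground truth for every assay, so each stage of the
    pipeline can be validated by recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
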