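Package: afmi
Title: Autofluorescence Multispectral Imaging Analysis of Ocular Surface Tissue
Version: 0.1.0
Authors@R:
    person("AFMI", "Maintainers", email = "afmi@example.org", role = c("aut", "cre"))
Description: Tools for sector-level analysis of autofluorescence multispectral
    image stacks of ocular surface tissue (normal conjunctiva, pterygium, and
    ocular surface squamous neoplasia). Provides a 59-channel spectral scheme,
    a synthetic tissue-phantom generator with realistic camera degradations,
    image preprocessing (background subtraction, flat-field correction, bad
    pixel repair, tile stitching), 16x16-pixel sector spectral signatures, a
    per-patient relative-signature normalization feeding a fused inter-patient
    PCA + SVM classification framework, intra-patient boundary delineation
    with red/orange/green false-color maps, and per-channel nonparametric
    group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
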