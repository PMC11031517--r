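Package: panospec
Title: Simulation of Spectral Panoramic Dental Radiographs from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spectral panoramic dental imaging from head CT volumes
    or synthetic labeled head phantoms. A head volume in Hounsfield units is
    segmented into air, soft tissue and bone, the dental arch is fitted and a
    panoramic source/detector sweep is constructed, and each basis material is
    forward projected with exact Siddon ray tracing to panoramic equivalent
    thickness images (PETI). From the thickness images the package synthesizes
    conventional polychromatic panoramic radiographs via the Beer-Lambert law
    with a filtered tungsten tube spectrum, virtual monoenergetic panoramic
    images (PVMI) at arbitrary energies, and the exact two-energy
    basis-material decomposition inverse. A reader-study module aggregates
    ordinal image-quality scores and compares modalities against a baseline
    with the Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
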