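Package: scmsi
Title: Microscopy-Integrated Single-Cell MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for single-cell lipidomics by
    transmission-mode MALDI-2 mass spectrometry imaging (MSI) integrated
    with fluorescence microscopy. Implements the in-source microscopy
    math (variance-of-Laplacian autofocus, radial-basis focal-surface
    interpolation, mosaic stitching, stage-scale calibration, teaching
    point export), two-stage multimodal co-registration (landmark
    translation initialisation followed by affine mutual-information
    refinement), mask-based compilation of single-cell and subcellular
    mass spectra with fractional pixel coverage, accurate-mass lipid
    annotation with adduct calculus and ion-mode curation, and spatial
    single-cell statistics (marker classification, k-means tissue
    microenvironments, UMAP+DBSCAN subtyping, edge-distance neighborhood
    analysis). Ships a synthetic multimodal phantom generator so the
    whole pipeline is testable end-to-end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    xml2,
    uwot,
    cluster,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
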