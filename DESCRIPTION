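Package: mctsnuclei
Title: Single-Cell Nuclear Cytometry of Multicellular Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end single-cell analysis of DNA-stained multicellular
    tumor spheroids imaged as confocal z-stacks: three-stage 3D seeded
    watershed nuclear segmentation with seed pruning and programmatic seed
    injection, per-nucleus volumetric and integrated-intensity measurement,
    DNA-content image cytometry with depth correction and per-spheroid
    median normalization, cell-cycle classification by an optimal
    TPR-FPR threshold and by a radial-basis-function support vector
    machine on neighbor-normalized volumetrics, and spheroid spatial
    organization metrics (perimeter distances, concentric layers,
    nuclear alignment angles, radial trends). Ships a ground-truthed
    synthetic spheroid phantom generator so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
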