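Package: autofuse
Title: Automated 2D-3D Image Fusion of the Vertebral Column for
    Endovascular Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-based 2D-3D registration of a CT-derived digital X-ray
    projection of the lumbar vertebral column onto a single fluoroscopy
    frame, as used to initialise image-fusion roadmaps during endovascular
    aortic repair. Provides cone-beam C-arm projection geometry, digitally
    reconstructed radiograph (DRR) rendering, Hounsfield-threshold vertebra
    segmentation and pairing, a hierarchical (global lattice then local
    variable step-size coordinate-descent) affine search driven by an
    edge-strength correlation score, a programmatic edge-visibility
    feasibility check, pigtail-marker calibrated bone and vascular
    alignment measurement, and the accompanying study statistics
    (median/min-max summaries, Mann-Whitney U, two-way absolute-agreement
    single-measure ICC). A phantom module generates synthetic CT volumes,
    vessel trees and simulated fluoroscopy frames with known ground truth
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    RNifti,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
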