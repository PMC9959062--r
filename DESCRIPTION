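Package: tmjmorph
Title: Holistic 3D Morphometric Assessment of the Temporomandibular Joint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic, reproducible 3D assessment of temporomandibular
    joint (TMJ) remodeling from pre- and post-operative surface models and
    volumetric scans. Provides dual-frame rigid registration (trimmed
    iterative-closest-point surface registration of the mandibular rami and
    masked intensity-based voxel registration of the cranial base),
    landmark-driven anatomical partitioning of the condyle and glenoid fossa
    into four sub-regions, signed surface-distance maps, volumetric-change and
    minimum joint-space quantification, inter-observer reliability statistics
    (one-way random single-measure intraclass correlation with exact F
    confidence intervals, mean absolute differences, Bland-Altman limits of
    agreement, Fisher-z sample-size calculation), and a synthetic TMJ phantom
    generator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
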