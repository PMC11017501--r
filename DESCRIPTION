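Package: avleak
Title: Arteriovenous-Axis Analysis of Blood-Brain Barrier Leakage in 3D
    Two-Photon Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of blood-brain barrier leakage, perfused vessel
    density and vessel-type-resolved hemodynamics along the arteriovenous
    axis in three-dimensional intravital two-photon image stacks after
    photothrombotic stroke. Provides seed-guided minimum-cost vessel
    centerline tracing, intensity-constrained lumen filling, separation of
    luminal from extraluminal tracer signal, parenchyma/subarachnoid
    compartment segmentation, full-width-at-half-maximum vessel diameter
    measurement, rule-based arteriovenous vessel classification,
    nearest-wall attribution of local leak sites, station-sampled
    spreading-distance measurement, two-timepoint leak progression, and an
    infarct-volume formula for serial sections. A synthetic-phantom module
    generates 3D two-photon-like stacks with known vascular geometry,
    tracer leakage, occlusion and constriction so that every stage is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    mgcv
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'phantom-spec.R'
    'phantom-generate.R'
    'phantom-cylinder.R'
    'phantom-render.R'
    'tracing.R'
    'leakage.R'
    'avaxis-diameter.R'
    'avaxis-classify.R'
    'avaxis-leaks.R'
    'infarct.R'
    'io-stack.R'
    'io-swc.R'
    'io-roi.R'
    'pipeline.R'
    'recovery.R'
    'RcppExports.R'
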