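Package: spiralPVM
Title: Spiral Phase Velocity Mapping Analysis of Myocardial Motion
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for retrospectively gated spiral myocardial
    phase velocity mapping. Generates ground-truthed synthetic
    velocity-encoded short-axis image series from a moving left-ventricular
    annulus phantom, reconstructs calibrated three-directional velocity
    fields (phase differencing, retrospective-gating interpolation to 60
    cardiac phases, stationary-phantom background correction), designs and
    grids interleaved spiral k-space trajectories, decomposes velocities
    into the cylindrical system natural to the left ventricle with AHA and
    24-segment regional partitions and transmural layers, quantifies named
    systolic, early-diastolic and atrial-systolic velocity peaks with
    time-to-peak values normalised to systolic and diastolic length, builds
    cohort-averaged phase-normalised colour maps, and assesses inter-study
    reproducibility with signed differences and Bland-Altman statistics.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'acquisition-params.R'
    'motion-model.R'
    'phantom.R'
    'navigator.R'
    'spiral.R'
    'gridding.R'
    'velocity-recon.R'
    'lv-geometry.R'
    'segments.R'
    'curve-analysis.R'
    'cohort-maps.R'
    'reproducibility.R'
    'pipeline.R'
    'io.R'
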