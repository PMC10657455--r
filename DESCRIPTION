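Package: cystmorph
Title: 3D Subcellular Morphometry of Snow-Alga Cysts from Volume Electron Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mesh-based morphometry for segmented volume-electron-microscopy
    reconstructions of Sanguina nivaloides cysts and similar single cells.
    Provides triangle-mesh and label-volume containers with validity checking,
    surface-area and signed-volume metrics, isosurface extraction from label
    volumes, BVH-accelerated inter-organelle proximity mapping with thresholded
    surface-area fractions, HC Laplacian smoothing with wrinkle area-gain and
    curvature-based membrane-ridge quantification, scene-level occupancy and
    ratio reports, a synthetic organelle-scene generator for end-to-end testing,
    and PAM chlorophyll-fluorescence parameter computation (Y(II), NPQ, rETR,
    Fv/Fm) together with snow liquid-water-content renormalisation of ionomic
    concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'curvature.R'
    'icosphere.R'
    'labels-to-meshes.R'
    'mesh-io.R'
    'mesh-metrics.R'
    'mesh-validate.R'
    'morphometry.R'
    'pam.R'
    'pipeline.R'
    'proximity.R'
    'scene-io.R'
    'smoothing.R'
    'synthetic-scenes.R'
    'volume-io.R'
    'wrinkles.R'
    'zzz.R'
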