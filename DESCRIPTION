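Package: fluorovol
Title: Fluoroscopic 3D Image Estimation from 4D-CBCT PCA Motion Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates fluoroscopic (time-resolved) volumetric images from a
    patient-specific respiratory motion model derived from four-dimensional
    cone-beam CT (4D-CBCT), driven frame-by-frame by single cone-beam
    projections. Implements the full chain: marker-free respiratory signal
    extraction from projections (Amsterdam shroud), phase sorting, short-scan
    FDK reconstruction of phase bins, Demons deformable registration to a
    peak-exhale reference, principal-component decomposition of the resulting
    displacement vector fields, and per-projection gradient-descent estimation
    of the mode coefficients that deform the reference volume to match each
    incoming projection. Ships a deformable digital thorax phantom and
    cone-beam acquisition simulator with known ground-truth tumor motion, so
    the whole pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
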