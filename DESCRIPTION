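Package: cbctmotion
Title: Simulation and Analytic Modeling of Mobile-Target Elongation in
    Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator of cone-beam computed tomography (CBCT)
    acquisition of a mobile thorax phantom, together with the closed-form
    model of motion-induced target elongation along the superior-inferior
    axis: L = L0 + Vp*T for constant-speed motion and L = L0 + 2A for
    cyclic motion whose period is shorter than the scan. Provides a
    voxelized three-target digital phantom, sinusoidal and constant-speed
    rigid motion, a time-resolved cone-beam forward projector, Feldkamp
    (FDK) filtered backprojection with Parker short-scan and
    displaced-detector half-fan weighting, an arcsine dwell-density
    "occupancy blur" surrogate, FWHM-style profile length measurement, and
    experiment drivers that sweep range of motion, frequency, phase and
    scan mode and compare measured apparent lengths with the model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
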