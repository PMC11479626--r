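Package: edfrim
Title: Extended Depth of Field Random Illumination Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction tools for extended depth of field
    random illumination microscopy (EDF-RIM). Builds scalar-diffraction optical
    models (pupils, 3D and extended-depth point spread functions), synthesizes
    3D and Bessel-type speckle illuminations from random-phase pupil masks,
    simulates speckled acquisitions of surface-distributed fluorescent samples
    with photon noise, reconstructs super-resolved projective images by
    Tikhonov-regularized variance matching, estimates sample surface topography
    from a plane-by-plane scan by robust RANSAC fitting, and projects the
    reconstructed image onto the estimated surface for 3D rendering. Includes a
    Siemens-star resolution readout and phantom generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
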