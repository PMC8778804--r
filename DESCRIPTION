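Package: inertiaCT
Title: Inertial Properties of Scanned Specimens from Calibrated Computed
    Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates three-dimensional centre of mass, inertia tensors and
    principal axes of scanned specimens from computed tomography volumes.
    Grey-values are converted to absolute density through a per-scan linear
    calibration against tissue characterisation phantoms; the specimen is
    segmented by a threshold optimised so the calibrated mass matches the
    balance-measured mass; voxel mass models then yield centre of mass,
    inertia tensors about arbitrary origins and axes, virtual dissection
    into anatomical segments, projected mass and moment-of-inertia maps and
    spanwise profiles.  Includes the trifilar-pendulum measurement model
    (damped harmonic oscillator fitting of gyroscope traces, period-based
    moment of inertia, centre-of-mass misalignment correction) used to
    validate CT estimates, and a synthetic-scene generator with analytic
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    minpack.lm,
    tiff,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
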