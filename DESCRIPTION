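Package: coilsteer
Title: Selective Magnetic Stimulation of Multifascicular Peripheral Nerve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation stack for selective magnetic stimulation of a
    multifascicular peripheral nerve with an array of four mm-scale solenoid
    coils. Builds a heterogeneous, anisotropic voxel model of the rat sciatic
    nerve, computes coil vector potentials and incident electric fields by
    Biot-Savart summation, solves the quasi-static induced field with an
    impedance-method (voxel network) solver, derives the axonal activation
    function dEx/dx on the nerve mid-plane, and tunes per-coil current weights
    to maximise recruitment selectivity of intraneural target regions.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
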