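Package: tevpblood
Title: Thixotropic Elasto-Visco-Plastic Constitutive Modelling of Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and calibration toolkit for a tensorial thixotropic
    elasto-visco-plastic (TEVP) constitutive model of whole blood. The model
    couples Saramito-type elasto-visco-plasticity with von Mises yielding, a
    linear Phan-Thien-Tanner stress function and a scalar structure parameter
    describing rouleaux aggregation and disaggregation kinetics. The package
    integrates the coupled stress/structure equations through standard
    rheometric protocols (steady and startup shear, cessation, intermittent
    rectangular steps, triangular ramps, exponential ramp-down, large-amplitude
    oscillatory shear, uniaxial extension), computes derived rheometric
    quantities (overshoot metrics, thixotropic index, apparent and extensional
    viscosity, the Morris yield-stress correlation, Lissajous-Bowditch and
    Pipkin diagrams, generalized-Newtonian comparator fits), and estimates the
    eleven model parameters by simultaneous nonlinear regression on steady and
    transient rheograms, including a synthetic-data generator for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
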