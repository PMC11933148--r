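Package: cardiocosim
Title: Multiscale Cardiovascular Co-Simulation via an FMI-Style
    Leader/Follower Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop univentricular (Norwood, modified Blalock-Taussig
    shunt) lumped-parameter haemodynamics packaged as a co-simulation
    follower in the style of the Functional Mock-up Interface (FMI) 2.0
    standard.  A zero-dimensional surrogate of the aortic arch and shunt
    region acts as the leader subsystem, exchanging boundary pressures and
    flows with the follower at every macro timestep; the follower
    integrates its circulation dynamics with an internally subdivided
    fixed-step fourth-order Runge-Kutta solver.  Includes FMU archive
    packaging and a structural compliance checker, a monolithic reference
    integrator for splitting-error studies, waveform analytics (cycle
    averages, Qp/Qs, range-normalised RMSE, pressure-volume loop metrics),
    and deterministic tuning of circulation parameters toward clinical
    haemodynamic targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
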