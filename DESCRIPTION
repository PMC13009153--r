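Package: rickerpp
Title: Dynamics and Bifurcations of a Discrete Ricker-Holling Predator-Prey Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and bifurcation analysis of a two-dimensional
    discrete-time predator-prey map combining Ricker prey growth with a
    Holling type II functional response and predator mortality. Provides
    exact fixed points and analytic Jacobians, jury-condition stability
    classification, closed-form and numerical location of period-doubling
    (flip) criticality, Neimark-Sacker normal-form data including the first
    Lyapunov coefficient, center-manifold reduction of the flip bifurcation,
    orbit simulation with divergence handling, attractor period detection,
    maximal Lyapunov exponents by tangent-vector propagation, and
    bifurcation-diagram generation with cascade detection. Includes the
    three study scenarios as packaged fixtures and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
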