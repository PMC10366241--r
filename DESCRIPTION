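Package: ephapsim
Title: Ephaptic Entrainment of a Quadratic Integrate-and-Fire Neuron
    with Membrane Damage
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates ephaptic (extracellular electric field) entrainment of
    a single quadratic integrate-and-fire neuron whose passive membrane
    properties can be degraded: a channel-inactivation fraction raises the
    specific membrane resistance and a bilayer-impairment fraction lowers the
    specific capacitance.  Provides a forward-Euler integrator with hard spike
    reset, sinusoidal local-field-potential stimulation through a point-source
    extracellular potential, spike-triggered averaging, spike-field coherence,
    and orchestration of calibrated frequency-sweep and damage-grid
    experiments that summarise entrainment-preference bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
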