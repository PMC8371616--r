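Package: ventsim
Title: Closed-Loop Simulation of a Bag-Based Emergency Ventilator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an acute-shortage mechanical ventilator built around a
    mechanically compressed self-inflating bag resuscitator, coupled to a
    configurable single-compartment lung model with optional spontaneous
    muscle effort. Implements volume- and pressure-controlled assist-control
    modes with patient triggering, an adaptive tidal-volume setpoint,
    mechanical peak-pressure and PEEP valves, orifice-spirometer sensing,
    and a clinical alarm system. Provides a hybrid plant/controller
    simulation engine, per-breath waveform analytics (tidal volume, peak and
    end-expiratory pressure, respiratory rate, I:E ratio, missed-trigger
    statistics), a preset scenario library spanning normal and ARDS lung
    mechanics, and CSV/YAML input and output with a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
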