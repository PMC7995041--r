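Package: oscvent
Title: Reduced-Order Simulation of a Fluidic-Oscillator Ventilator with a
    Windkessel Lung
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lumped-parameter simulator of an educational mechanical
    ventilator driven by a bistable fluidic oscillator and coupled to a
    single-compartment resistance-compliance (Windkessel) lung. The
    Coanda-effect jet switching of the oscillator is reduced to a
    pressure-threshold hysteresis element, giving a switched linear
    system that is integrated with event-located phase changes. Includes
    a patient inspiratory-effort (pleural pressure) trigger model, breath
    segmentation and respiratory indices (PIP, PEEP, period, respiratory
    rate, I:E ratio, tidal volume), calibration-screw parameter sweeps
    with a depth-period regression, a synthetic-waveform fixture
    generator, waveform CSV and YAML configuration I/O, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
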