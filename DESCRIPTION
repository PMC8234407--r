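Package: gazekit
Title: Eye-Movement Recognition from EOG and Forehead-Strain Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, conditioning and classification toolkit for
    gaze-controlled human-machine interfaces that read a forehead biosensor.
    Generates labeled synthetic two-channel trials (horizontal-saccade
    electrooculogram spikes and vertical-gaze skin-strain resistance events),
    emulates the analog front end (instrumentation gain, 48-52 Hz notch,
    10 Hz low-pass, A/D quantization), smooths traces with a scalar Kalman
    filter, separates the superimposed slow strain and fast saccade
    components with a thresholded multilevel wavelet decomposition, extracts
    amplitude/duration/interval features, and classifies the five gaze
    states (straight, up, down, left, right) with ten one-against-one
    Gaussian-kernel support vector machines aggregated through an interval
    decision score. Includes the reversed-row confusion-matrix accuracy
    conventions used in this device literature, a benchmark driver, sensor
    design calculators (cantilever stiffness, load-deflection pressure,
    Young's modulus, resistivity), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    kernlab,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
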