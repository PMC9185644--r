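Package: propulse
Title: Online Recognition of Wheelchair Propulsion Gestures from Wearable
    Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and times manual-wheelchair propulsion gestures from
    bilateral hand-worn inertial measurement units sampled at 30 Hz. Raw
    trials are segmented with a sliding window, each window is described by
    19 time- and frequency-domain features per input signal, and two
    per-side three-class classifiers (forward, backward, dance) are trained
    with univariate feature selection and grid-searched cross-validation.
    A deterministic fusion table rebuilds eight specific propulsion
    gestures from the two side predictions, a minimum-duration spike filter
    removes transient confusions, and propulsion count, onset time, and
    duration are reported against force-sensor reference boundaries. A
    synthetic choreography generator emulates instrumented wheelchair-dance
    trials for training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ranger,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
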