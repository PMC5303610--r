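Package: pulseloop
Title: Mock Circulatory Loop Simulation and Classification of Radial Pulse Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-silico mock circulatory loop for studying how the classical
    pulse qualities of oriental pulse diagnosis (depth, rate, shape and
    strength) arise from hemodynamics. A slider-crank piston pump drives a
    two-segment elastic vessel network (aorta and radial artery) terminated by
    a peripheral resistance; the radial pressure waveform is synthesised by
    delay-line superposition of the forward wave, its peripheral reflection
    and a valve-closure rebound transient. A tonometric hold-down protocol
    (stepped applied pressure) converts waveforms into P-H curves, from which
    the coefficient of floating and sunken pulse (CFS), pulse force and pulse
    power are computed and the pulse is labelled on each of the four axes.
    Includes a glycerin-water working-fluid model, Moens-Korteweg pulse wave
    velocity helpers, the mock-loop length-scaling design rule, named presets
    for the nine simulated pulse types, CSV/JSON interfaces and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
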