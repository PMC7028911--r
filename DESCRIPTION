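Package: shuntcheck
Title: Passive Skin-Electrode Contact Impedance Assessment via a Switched
    Shunt Resistor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing skin-electrode contact quality in biopotential
    acquisition systems (EEG, intraoperative neurophysiological monitoring)
    without injecting any current into the patient. A known shunt resistor is
    switched in parallel with each amplifier input and the attenuation of the
    measured biosignal itself, quantified as a ratio of settled RMS values
    over a four-phase switch sequence, is inverted to a contact resistance
    estimate and classified as good, middling or unacceptable. Includes
    closed-form models of the analog front end (input high-pass filter, shunt
    network, differential amplifier), a time-domain simulator of the full
    acquisition chain with switch transients, ADC quantization and noise,
    synthetic test-signal generators, and scripted validation experiments with
    tidy tabular outputs and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
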