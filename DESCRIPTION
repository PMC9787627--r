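Package: breathband
Title: Breathing Parameter Extraction from Dual-IMU Differential Acceleration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a differential inertial pipeline for wearable breathing
    monitoring. Two triaxial accelerometers, one on the chest and one on the
    back, are combined into a differential acceleration-magnitude signal in
    which body-motion components common to both sensors cancel and the
    breathing modulation survives. The signal is low-pass filtered with a
    causal Butterworth filter and segmented into inhalation/exhalation phases
    by a streaming dispersion (smoothed z-score) peak detector; debounced
    exhalation events yield per-window respiration rate, inhalation and
    exhalation times, their ratio, and an estimated flow rate based on ideal
    body weight. Includes a seeded synthetic dual-IMU scenario generator with
    ground truth for validation, and Pearson/Bland-Altman/mean-absolute-error
    agreement statistics for comparing device output against a reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
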