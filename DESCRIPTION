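Package: orthomon
Title: Multimodal Monitoring of Cardiovascular Responses to Postural Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for multimodal cardiovascular recordings
    (photoplethysmography, electrocardiography, near-infrared spectroscopy
    and continuous finger blood pressure) around postural changes.
    Provides a ground-truth hemodynamic simulator, inter-device
    synchronization via a shared pulse-train reference channel, signal
    preprocessing and automated quality gating, two-stage pulse-wave-velocity
    extraction, PPG-based blood-pressure estimation by leave-one-repeat-out
    linear regression, drop-method baroreflex sensitivity and NIRS-based
    cerebral autoregulation estimates, sequence-method baroreflex statistics,
    and intraclass-correlation reliability and validity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
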