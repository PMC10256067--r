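Package: halluxgrip
Title: Hallux Contact-Force Decoding and Posture Control for an Assistive Hand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free pipeline for controlling a single-degree-of-freedom
    assistive (prosthetic) hand from plantar contact-force signals measured by
    a smart insole. Simulates multi-channel insole force traces (gait peaks in
    heel/forefoot channels, deliberate big-toe presses in the hallux channel),
    smooths them with a recursive-average plus scalar Kalman filter fusion,
    decodes deliberate toe presses per scan window with a threshold-crossing
    peak-count statistic, calibrates a polynomial interfinger-distance to
    opening-time-ratio model with SSE/R-squared model-order selection, and
    drives a simulated hand through a press-count to posture code via timed
    open/close line commands, including closed-loop daily-activity scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
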