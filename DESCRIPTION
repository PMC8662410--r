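Package: xdfstream
Title: Synchronized Multi-Sensor Streaming, XDF Recording and Post Hoc
    Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale re-implementation of a Lab Streaming Layer style
    acquisition stack for multimodal physiological sensor data. Provides an
    in-process stream transport with NTP-style round-trip clock-offset
    measurement, a fault-tolerant chunked recorder that writes Extensible
    Data Format (XDF) files with buffered flushes and a fixed clock-offset
    cadence, a bit-exact XDF reader that copes with truncated (killed)
    recordings, post hoc synchronization tools (offset interpolation,
    timestamp dejittering, effective sampling rate estimation, gap detection,
    resampling onto a common grid), and virtual devices with drifting,
    jittered clocks and load-dependent effective sampling rates for fully
    reproducible end-to-end validation scenarios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
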