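Package: wristflow
Title: Reconstitute and Preprocess Chunked Wristband Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reads fragmented raw-data chunk files from Empatica
    EmbracePlus-style wristband wearables (Avro object-container files or
    their direct CSV conversion), discovers recordings in the standard
    date/subject-device folder hierarchy, and reconstitutes them into
    unified, time-zone-aware physiological timeseries (electrodermal
    activity, blood volume pulse, skin temperature, accelerometry, systolic
    peak events and event tags) over default per-day or custom time windows.
    Provides a preprocessing suite (resampling, detrending including
    smoothness-priors, moving and Butterworth filters, sliding-window
    artifact detection, gap interpolation, z-scoring), event-tag editing,
    epoching, and export to MAT or XLSX. A synthetic device-data generator
    produces realistic multi-day, multi-subject chunked datasets so the
    whole pipeline can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    pracma,
    signal,
    stats,
    utils,
    graphics,
    yaml,
    zip,
    optparse
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
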