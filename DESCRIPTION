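Package: fieldmon
Title: Distributed Field-Phenotyping Data Collation and Microclimate Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulator-backed information-management stack for distributed
    plant-phenotyping experiments. A device-side agent scores, selects and
    downsizes daily crop images, logs hourly microclimate readings, and
    synchronizes signed JSON payloads to a collation server with
    store-and-forward buffering across network outages. The server
    authenticates and idempotently ingests payloads into a SQLite store,
    classifies device health, and assembles grid and per-device views with
    CSV and monthly Zip exports. A climate-analytics layer interpolates
    plot-grid microclimate by inverse-distance weighting, builds heat-map
    time series, cross-validates sensors leave-one-out, and detects
    Smith-Period late-blight risk windows. A field simulator generates
    seeded weather, procedural canopy images, device lifecycles and fault
    schedules so the whole stack is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    lubridate,
    jsonlite,
    openssl,
    png,
    Matrix,
    zip,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
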