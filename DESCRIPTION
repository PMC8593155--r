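Package: vaesurv
Title: Automated Surveillance of Ventilator-Associated Events from ICU
    Measurement Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the CDC NHSN ventilator-associated event (VAE)
    surveillance algorithm for tiers I (ventilator-associated condition,
    VAC) and II (infection-related ventilator-associated complication,
    IVAC) on raw intensive-care measurement streams. Derives mechanical
    ventilation episodes from end-tidal CO2 measurement continuity,
    cleans respiratory signals with a percentile low-outlier rule,
    collapses measurements to CDC daily summary values, detects and
    tiers events, and computes validation statistics (confusion-matrix
    metrics), incidence rates per 1000 ventilator days with exact
    Poisson intervals, and yearly incidence trends by Poisson
    regression. A seeded synthetic-ICU generator with embedded
    ground-truth events makes the full pipeline testable without
    hospital data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
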