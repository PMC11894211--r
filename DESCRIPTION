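Package: riceSoS
Title: Rule-Based Rice Area and Start-of-Season Mapping from Multi-Temporal SAR Backscatter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for mapping paddy rice and its Start of Season (SoS) from
    multi-temporal C-band SAR VH backscatter time series. Provides a synthetic scene
    simulator with known per-pixel truth (gamma speckle, atmospheric spikes, field-level
    planting dates), temporal-signature conditioning (multi-temporal speckle filtering and
    anomaly interpolation), a parameterized rule-based rice classifier driven by thresholds
    extracted from training-field dB curves, SoS retrieval at the acquisition cadence,
    district-level area accounting in hectares, and thematic-map accuracy assessment
    (error matrix, overall/producer's/user's accuracy, kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
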