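Package: broodcast
Title: Short-Term Forecasting and Early Warning for Broiler-House Thermal Environment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monitoring, short-term forecasting and dual-indicator early warning
    for the thermal environment of cage-rearing broiler houses. Raw multi-source
    sensor streams (an inspection robot, fixed indoor points and an outdoor
    point) are aligned to a common 3-second grid, filtered against sensor
    ranges, aggregated to 5-minute means and gap-filled. Two indicators are
    derived: the temperature deviation (TD) between indoor and age-dependent
    target temperature, and the temperature-humidity index (THI). A hybrid
    Wavelet-ECA-GRU model - causal sliding-window discrete wavelet features,
    efficient channel attention and a gated recurrent unit - produces rolling
    30-minute-ahead forecasts of both indicators, which feed threshold-based
    heat/cold-deviation and THI risk-level warnings with age-dependent
    environmental-state rules. A seeded synthetic-house simulator generates
    realistic multi-source streams for end-to-end testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
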