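Package: hdssgeo
Title: Geospatial Surveillance Analysis for Rural Demographic Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and analysing georeferenced demographic
    surveillance sites in rural settings. Generates synthetic villages with
    realistic settlement morphology (clustered, linear, circular, regular),
    sector subdivision, socially structured household populations and
    environmental hazard (waste spot) layers; computes nearest-neighbour
    settlement typology, sector waste density and household proximity to
    hazards; classifies sectors by caste and socioeconomic dominance; runs
    rank-based association tests and regression-based mediation (path)
    analysis with cluster bootstrap; and implements ground-truthing
    quality-audit designs (stratified pilot sampling, lot quality assurance
    sampling, error-rate reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
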