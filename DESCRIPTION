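Package: reefheat
Title: Reef-Flat Heat Budgets, Bulk Air-Sea Fluxes, and Coral Bleaching Archives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing thermal stress events on shallow coral reef
    flats. Computes bulk air-sea heat fluxes (shortwave, longwave, latent,
    sensible) from meteorological station records, converts fluxes to heating
    rates over a shallow water column, and estimates the advective heat-flux
    component as the residual between observed and air-sea heating. Includes
    tidal harmonic synthesis, major-axis regression for current-meter
    cross-calibration, SST climatologies, anomalies and decadal trends,
    benthic point-count survey statistics, annual density-band and stress-band
    detection in coral skeletal cores, and a synthetic-data module that
    generates met forcing, forward-simulated reef temperature with a known
    flux decomposition, skeletal density profiles, and survey point counts for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
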