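Package: specpop
Title: Dual Field-of-View Spectral Processing and Early-Season Plant
    Population Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Processing chain for dual field-of-view canopy spectroscopy and
    chemometric estimation of early-season soybean plant populations. Converts
    four-frame measurement sequences (upwelling/downwelling target and dark
    frames) into illumination-invariant relative reflectance, normalising for
    dark current, integration time and fibre throughput; smooths and resamples
    spectra to a 400-900 nm, 5 nm analysis grid with plot averaging; screens
    all normalized difference spectral index (NDSI) band pairs against measured
    populations; and fits resampled partial least squares regression (PLSR)
    ensembles with calibration/cross-validation/validation reporting. Includes
    a synthetic instrument and canopy simulator (solar-like vs. overcast
    illumination, soil-vegetation mixtures with saturating fractional cover,
    shot noise, dark current) so the whole pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
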