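Package: mptet
Title: Modified Priestley-Taylor Evapotranspiration from Optical and
    Thermal Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-pixel daily crop evapotranspiration from
    Landsat-style surface-reflectance bands, a land-surface-temperature
    raster and overpass-time reanalysis meteorology, with no ground
    observations.  Implements a clear-sky surface radiation balance
    (broadband albedo, beam/diffuse transmissivity, atmospheric and
    surface emissivity), a mid-day soil heat flux ratio, the
    surface-temperature / vegetation-fraction triangle with fitted dry
    and wet edges, two-step linear interpolation of the Priestley-Taylor
    coefficient, evaporative-fraction upscaling of instantaneous latent
    heat flux to daily ET, and a five-statistic validation protocol
    (R2, RMSE, Willmott agreement index, Nash-Sutcliffe efficiency,
    mean bias error).  Includes a synthetic scene generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
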