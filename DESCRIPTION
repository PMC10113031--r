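Package: ecolag
Title: Lagged Environmental Drivers of Vertebrate Population Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects ecological time lags between environmental change and
    vertebrate population trends. Computes Living Planet Index style population
    trends (mean annual log10 rates of change) from abundance time series,
    derives lag-offset rates of climate warming and anthropogenic land-use
    change, scans exhaustive grids of year- and generation-based lag
    combinations with linear mixed-effects models ranked by AICc, averages
    retained models by Akaike weight, and projects decadal abundance indices
    under diverging socio-economic scenarios. Includes a synthetic-data
    generator emulating Living Planet Database population records and gridded
    environmental series with known ground-truth lag structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    mgcv,
    stats,
    utils,
    jsonlite,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
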