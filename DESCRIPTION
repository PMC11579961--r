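Package: coralight
Title: Light and Temperature Limitation of the Latitudinal Range of Coral Reefs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A latitude-resolved box model of shallow-water coral calcification.
    Daily solar irradiance is computed from orbital geometry (declination and
    sunset hour angle), attenuated through the water column by the Lambert-Beer
    law, and converted to a calcification potential through a hyperbolic-tangent
    photosynthesis-irradiance response, a dark-day tolerance rule, and a
    sea-surface-temperature envelope. The package generates synthetic meridional
    SST scenarios spanning modern-like to hothouse-like gradients, produces
    normalized latitudinal calcification profiles, runs parameter sweeps, and
    fits the dark-day threshold and tolerance that reproduce a given poleward
    cutoff of reef occurrence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
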