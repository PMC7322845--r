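Package: trackscape
Title: Predator-Level Isoscapes from GPS Tracks and Plasma Stable Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns concurrent GPS tracks and blood-plasma delta13C/delta15N
    values of central-place foraging seabirds into species- and guild-level
    isoscapes. Implements trip segmentation, speed filtering, regular-interval
    interpolation (linear and continuous-time correlated random walk),
    behavioural state classification (quadrant-constrained Gaussian-mixture
    clustering of speed and turning angle; species mean-speed rule for
    divers), lipid normalization of delta13C from C:N ratios, time-weighted
    mean foraging locations, ordinary kriging with weighted-least-squares
    variogram fitting, bootstrap guild ensemble surfaces, sea-surface-height
    front extraction, water-zone classification, and regression
    back-calculation of front isotope values. Includes a synthetic-data
    generator (correlated-random-walk tracks over latitudinal isotope
    gradients) so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
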