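Package: harrierIBM
Title: Spatially Explicit Individual-Based Model of Hen Harrier
    Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An annual-cycle, individual-based simulator of hen harrier
    (Circus cyaneus) population dynamics on a 1-km raster landscape.
    Birds select breeding territories in two stages (landscape-scale
    square then cell) by roulette-wheel sampling of prey-, occupancy-
    and distance-weighted scores; breeding females on managed grouse
    moor suffer persecution mortality; reproduction, winter mortality
    and an end-of-year clean-up complete the cycle.  The package loads
    or synthesises the five raster input layers (meadow pipit abundance,
    heather-burning index, habitat suitability, heath area, altitude),
    runs replicated multi-year scenarios, computes the standard output
    statistics (breeding pairs by region and habitat class, breeding
    success, fledgling production, density maps), and provides
    elasticity and two-parameter factorial experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
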