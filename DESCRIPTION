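Package: grasscape
Title: Individual-Centred Grass Growth Simulation and Functional-Trait
    Adaptive Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-step, individual-centred simulator of temperate grass
    growth coupling carbon-nitrogen substrate dynamics (photosynthesis,
    root N uptake, respiration, reserve storage and remobilisation) with
    shoot and root morphogenesis (leaf cohort demography, tillering with
    self-thinning) under climate drivers and cutting/fertilisation
    management.  Provides a virtual-experiment engine that sweeps
    factorial grids over four functional traits (specific leaf area,
    plant height, leaf lifespan, tiller density) at contrasting nitrogen
    supplies, and landscape analysis tools to locate adaptive peaks, fit
    adaptive ridges and their slopes, summarise trait coordination,
    compare predicted and observed trait syndromes by reduced major axis
    regression and principal component analysis, and predict plastic
    trait responses to nitrogen deprivation.  Includes seeded generators
    for species archetypes, daily weather and management schedules so the
    full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
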