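Package: stratmaze
Title: Stochastic Characterization of Navigation Strategies in Circular
    Hole-Board Mazes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing and modelling rodent navigation in automated
    variants of the Barnes maze, where trials are sequences of visits to
    peripheral vestibules ending at a goal. Provides trajectory segmentation
    into vestibule-visit sequences, the summary distributions that
    characterize them (trial length, vestibule occupancy, signed segment
    size, serial bout length), three stochastic strategy processes (random,
    spatial, serial), a strategy mixture model with persistence fitted by
    exhaustive grid search on distribution mean squared error, a four-state
    Markov chain strategy model fitted by a genetic algorithm, a rule-based
    trial classifier, and a synthetic experiment generator for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
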