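Package: ResistCA
Title: Cellular-Automata Modelling of Insecticide Resistance Spread in
    Malaria Vectors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Dynamic spatio-temporal modelling of confirmed phenotypic
    insecticide resistance in malaria vector populations on a regular
    geographic lattice. Implements an extended cellular automaton in
    which confirmed resistance spreads through Moore neighbourhoods
    gated by declarative threshold rules over environmental,
    agricultural and intervention driver layers, and can additionally
    emerge spontaneously in any cell whose local conditions permit it.
    Includes WHO bioassay-mortality state classification, exploratory
    driver-selection statistics (Pearson correlation, chi-square
    association, principal-component retention, correlation-distance
    clustering), confusion-matrix accuracy validation against
    georeferenced susceptibility records, threshold calibration, and a
    seeded synthetic-data generator with a planted ground-truth rule
    set for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
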