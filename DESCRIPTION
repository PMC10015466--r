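Package: fetiron
Title: Speciation, Relaxometry and Dissociation Kinetics of the Iron(III)-Tiron System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward models and fitting tools for characterizing the
    Fe(III)-Tiron system in aqueous solution: multi-equilibrium pH speciation
    with refinement of stability constants from spectrophotometric and
    potentiometric titrations; water-proton relaxivity as the sum of inner-,
    second- and outer-sphere (Freed) contributions with Solomon-Bloembergen-
    Morgan theory and transient zero-field-splitting electron relaxation;
    Swift-Connick analysis of variable-temperature 17O transverse relaxation
    rates and shifts; simultaneous (global) fitting of 1H NMRD profiles and
    17O data with shared parameters; and pseudo-first-order analysis of
    CDTA-mediated transchelation kinetics. A synthetic-data generator with
    known ground truth supports end-to-end testing of every fitting route.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
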