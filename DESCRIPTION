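Package: recurasim
Title: Pharmacokinetic-Pharmacodynamic Simulation of Rocuronium Reversal
    by Sugammadex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation of neuromuscular blockade by rocuronium
    and its reversal by sugammadex. Implements free-drug and 1:1
    rocuronium-sugammadex complex disposition as linear two-compartment
    models coupled by molar binding kinetics, an effect-compartment (ke0)
    link, and a train-of-four (TOF) pharmacodynamic mapping. Includes an
    emulation of a closed-loop TOF-guided rocuronium infusion controller
    with a stepped sugammadex reversal protocol, a synthetic patient cohort
    generator, device-style dosing-record input/output, and analysis of
    post-reversal effect-site concentration rebound (recurarization risk).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
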