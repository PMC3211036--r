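Package: isetlogp
Title: Semi-Empirical Electrotopological Index for Octanol/Water log P
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the semi-empirical electrotopological index (I_SET), a
    single whole-molecule descriptor for aliphatic organic compounds built
    from per-atom electronic-state values (derived from semi-empirical net
    atomic charges) aggregated over the hydrogen-suppressed molecular graph,
    with a dipolar correction for heteroatom-containing molecules. Provides
    per-class linear calibration of the descriptor against experimental
    octanol/water partition coefficients (log P), leave-one-out
    cross-validation (PRESS, q2), external test-set validation with
    observed-versus-predicted and through-origin regressions, packaged
    reference datasets of 141 aliphatic compounds across five classes plus
    seven external alcohols, a seeded synthetic-data generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
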