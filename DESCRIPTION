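Package: diazodiel
Title: Diel Photophysiology and Electron Budgets of Unicellular Diazotrophs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for diel photophysiology experiments on
    unicellular nitrogen-fixing cyanobacteria (Crocosphaera, Cyanothece).
    Computes chlorophyll-normalized electron transport rates from fast
    repetition rate fluorometry yields, fits Eilers-Peeters
    photosynthesis-irradiance curves, converts 14C scintillation counts to
    carbon-incorporation rates, derives gross oxygen evolution from
    electrode measurements, converts acetylene-reduction ethylene series to
    nitrogen-fixation rates, and assembles phase-integrated electron budgets
    (electron demand per carbon and per N2 fixed). Includes the CFM-CC
    linear growth model for two-species competition over a nutrient
    repletion factor, a seeded synthetic diel-data generator with known
    ground truth for pipeline validation, and a config-driven command-line
    entry point.
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
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
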