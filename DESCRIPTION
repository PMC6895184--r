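Package: uvvisdb
Title: Curation and Validation of a Comparative UV/Vis Absorption Database
Version: 0.1.0
Authors@R:
    person("UVVis", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to build, filter and validate a comparative database of
    experimental and computed UV/vis absorption attributes. Parses multi-valued
    wavelength and extinction-coefficient table cells (plain, standard-form and
    logarithmic units) and pairs them by index into peak objects; applies a
    rule-based opto-electronic filter to SMILES strings (sanitization and
    canonicalization, heavy-metal and charge rejection, pi-conjugation
    detection, alkyl-chain trimming, electron counting and HPC band
    assignment); models compound records with PRISTINE experimental and
    FILTERED computational branches with JSON and CSV (de)serialization and
    InChIKey deduplication; and provides the technical-validation statistics
    suite (histograms and their intersection, subsample stability, extinction
    range and percentile flagging, oscillator-strength conversion, mean
    absolute error, regression with confidence bands, quartile summaries, rank
    correlation and solvent tallies) together with a seeded synthetic-data
    generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, on the PATH as 'python'
Config/testthat/edition: 3
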