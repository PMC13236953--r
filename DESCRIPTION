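Package: whiteflysim
Title: Stage-Structured Population Dynamics of Cassava Whitefly Under RNAi Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Temperature-driven daily Leslie-matrix model of Bemisia tabaci
    (SSA1-SG1) population dynamics on cassava, with density-dependent adult
    mortality, calibration of lab-derived vital rates to field adult-emergence
    levels, transgenic RNAi treatment effects on nymph development and adult
    survival, and a two-patch extension coupling non-transgenic and transgenic
    plots by adult migration. Includes scenario grids over treatment intensity,
    stage targeting and landscape coverage, a synthetic-data module that
    generates life tables, tropical temperature series and sequence fixtures,
    and an exact 21-mer off-target screen of candidate dsRNA sequences against
    reference panels on both strands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
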