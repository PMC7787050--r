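Package: mucotrace
Title: Stable-Isotope Tracer Accounting for Fish Skin-Mucus Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dietary stable-isotope (13C/15N) tracer studies of fish
    skin mucus and reference tissues. Converts EA-IRMS delta notation to isotope
    ratios and atom percent against the VPDB and AIR standards, computes atom
    percent excess (APE) against natural-abundance blanks, allocates tracer as
    percent of ingested dose to tissues and mucus fractions, summarises mucus
    exudation per skin area and per body mass, and applies the
    Levene/ANOVA/Tukey/Dunnett-T3 testing ladder with compact-letter displays.
    Includes a calibrated pulse-chase cohort simulator for the time-course and
    mucus-renewal designs so every pipeline stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
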