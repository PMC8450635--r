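Package: paleoprev
Title: Parasitism Occurrence and Prevalence Versus Host Diversity Across the Phanerozoic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for macroevolutionary analyses of marine parasitism in the
    fossil record. Reads species-level parasitism occurrence tables and
    Paleobiology-Database-style genus occurrence exports, bins records onto a
    period-level Phanerozoic timescale, computes per-occurrence parasite
    prevalence with era-level medians, bootstrap confidence intervals and
    Mann-Whitney comparisons, estimates coverage-standardized (shareholder
    quorum subsampled) mean sampled diversity and three-timer origination and
    extinction rates per period, and relates parasitism to those diversity
    indices through specimen-weighted Poisson and binomial generalized linear
    models classified as supporting amplification or dilution of parasitism
    with host diversity. A synthetic-data module simulates fossil records and
    parasitism databases with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
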