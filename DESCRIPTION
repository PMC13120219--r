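Package: domlake
Title: Biodegradation Dynamics of Lake Dissolved Organic Matter
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the microbial degradation of dissolved
    organic matter (DOM) in lakes from molecular to bulk scale: molecular
    formula assignment and van Krevelen / CRAM classification of FT-ICR
    mass spectra, two-pool pseudo-first-order biodegradation kinetics for
    DOC and CDOM time series, nonnegative PARAFAC decomposition of
    excitation-emission fluorescence matrices with split-half validation,
    formula-set similarity and molecule fate tracking, and light 16S
    community ecology (Shannon diversity, Bray-Curtis, PCoA, abundance
    filtered Spearman screens). Includes seeded synthetic-data generators
    that emulate a 60-day incubation experiment so that every pipeline
    stage can be exercised and validated without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
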