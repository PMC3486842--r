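Package: catapot
Title: Phenomenological Prediction of Microbial Catabolic Potential and
    Biomass Yield
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a nutrient can serve as a sole carbon source
    for a microbe (a decision cascade over nutrient class, a small set of
    gating enzymes, and a logistic model over catabolic pathway membership),
    the biomass yield of single nutrients from their effective carbon
    content, and biomass production on complex media as an additive sum of
    per-class carbon yields.  Includes a small flux-balance-analysis engine
    (steady-state linear programming over a stoichiometric network) used to
    generate in silico growth labels and yields, forward model selection
    with AIC/BIC scoring, random complex-media ensemble generation, and
    synthetic fixture generators with planted structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
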