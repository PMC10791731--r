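Package: gyflux
Title: Dipeptide Feed-Media Analysis for CHO Fed-Batch Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying glycyl-L-tyrosine (GY) dipeptide
    feed-media effects on IgG-producing CHO fed-batch cultures. Computes
    per-phase specific rates (integrated viable cell density, specific growth
    rate, specific productivity and metabolite consumption/production rates)
    from culture profiles with feed correction, screens replicate bioreactors
    for outliers with a VCD standard-deviation band rule, fits batch-level
    partial least squares models of final titer with VIP scores and
    coefficient-sum nutrient ranking, and performs enzyme-capacity-constrained
    flux balance analysis of a dipeptide-augmented CHO-like metabolic network
    with fold-change-based comparative flux analysis. Includes a synthetic
    fed-batch culture generator and a reduced CHO-like network so the whole
    pipeline runs without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
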