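Package: arealrisk
Title: Bayesian Small-Area Disease Risk Mapping and Two-Wave Change Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for repeated small-area disease risk surveillance: indirect
    sex-standardization of area-level counts, Bayesian hierarchical smoothing of
    relative risks with a Besag-York-Mollie (ICAR + exchangeable) model fitted by
    Metropolis-within-Gibbs MCMC, posterior exceedance-probability certainty
    classification (red/yellow/green) and ranking, and detection of evidential
    positional changes in risk between two survey waves. Includes a synthetic-data
    generator with spatially correlated risk surfaces and planted changes, plus
    GAL neighbor-list and GeoJSON adjacency support, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
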