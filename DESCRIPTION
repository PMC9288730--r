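Package: asbdemand
Title: Price Elasticity, Affordability and Tax Simulation for Sugar-Sweetened Beverages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates own- and cross-price elasticities of aerated and
    sugar-sweetened beverages from clustered household expenditure surveys
    using Deaton's two-equation unit-value method, with corrections for
    quality shading and measurement error in unit values and cluster
    bootstrap standard errors. Includes a synthetic survey generator with
    known ground truth for validating the estimator, a relative income
    price (RIP) affordability analysis with a price/income decomposition,
    and a GST compensation-cess tax simulation for consumption-reduction
    targets under alternative pass-through scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
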