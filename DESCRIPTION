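Package: vaporisk
Title: Multi-Route Health Risk Assessment of E-Cigarette Aerosols and Liquids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic human health risk assessment for
    organic compounds and heavy metals measured in e-cigarette aerosols and
    e-liquids. Computes chronic daily doses for the inhalation, oral and
    dermal routes together with acute intakes, converts them to incremental
    lifetime cancer risks, hazard quotients and acute risk ratios against
    packaged regulatory reference values (REL, RfC, RfD, cancer potency and
    slope factors, LD50), and aggregates them into route-level hazard indices
    and total risks. A probabilistic layer fits candidate distributions to
    concentration samples by maximum likelihood with Anderson-Darling
    selection, propagates them through the risk pipeline by Monte Carlo
    simulation, and reports percentiles, exceedance probabilities and
    rank-correlation sensitivity contributions. Includes a synthetic
    literature-study generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    fitdistrplus,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    knitr,
    rmarkdown
Config/testthat/edition: 3
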