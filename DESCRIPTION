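Package: n2otracer
Title: Isotopologue Accounting and Rate Inference for 15N-Tracer N2O
    Incubations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying nitrous oxide (N2O) production by aquatic
    ammonia oxidizers from 15N-labeled tracer incubations. Converts calibrated
    45/44 and 46/44 molecular ion ratios into isotopologue amounts, estimates
    zero-order ammonia- and nitrite-oxidation rates from labeled nitrite and
    nitrate pool time series, computes N2O yields and isotope-dilution
    corrections, and attributes N2O formation to binomial pairing of
    ammonium-derived nitrogen, hybrid formation (one ammonium-derived and one
    nitrite-derived atom), or nitrifier denitrification. Includes acid-base
    speciation of the nitrogen pools, an abiotic N2O-forming kinetic network,
    air-water N2O equilibrium and saturation anomaly, and a synthetic
    incubation-experiment generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
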