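Package: stratbiogeo
Title: Time-Stratified Ancestral Range Estimation for Island Biogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Likelihood-based ancestral range estimation on dated phylogenies
    under the dispersal-extinction-cladogenesis family of models (DEC,
    DIVALIKE, BAYAREALIKE, each with an optional founder-event speciation
    parameter j), with time-stratified epoch-specific dispersal multiplier
    matrices. Ships the five-area Caribbean epoch presets used to evaluate
    the GAARlandia land-bridge hypothesis, a downstream chronology layer
    (divergence-time window tests, literature-age concordance, ancestral
    origin summaries), simulators for dated Yule trees and range evolution,
    and a full model-selection pipeline with AIC and Akaike weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
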