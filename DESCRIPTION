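Package: watrisk
Title: Non-Carcinogenic Health Risk Assessment for Drinking-Water Contaminants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic non-carcinogenic health risk
    assessment for contaminants ingested through drinking water. Computes
    estimated daily intake (EDI), hazard quotients (HQ) and hazard indices
    (HI) per brand and age group from measured concentration panels,
    screens concentrations against guideline bounds, propagates parameter
    uncertainty by Monte Carlo simulation with lognormal/normal/point
    marginals, and ranks input variables by contribution to variance using
    squared Spearman rank correlations. Ships the measured fluoride and
    nitrate concentrations of 22 bottled-water brands and the four-age-group
    exposure parameter set used throughout, plus a synthetic panel generator
    with known ground truth for property testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
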