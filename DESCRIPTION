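Package: medfire
Title: Non-Stationary Climate-Fire Models for Mediterranean Summer Burned Area
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates per-eco-region drought to burned-area regressions
    driven by the Standardized Precipitation-Evapotranspiration Index (SPEI),
    models the spatial variation of drought sensitivity as a function of
    long-term climate normals, and projects summer burned-area changes at
    1.5, 2 and 3 degrees Celsius of global warming with stationary and
    non-stationary model variants. Includes Hargreaves potential
    evapotranspiration, log-logistic SPEI standardization against a fixed
    reference period, linear-scaling bias correction of climate-model output,
    spatially coherent bootstrap significance testing with false discovery
    rate control, robust (IRLS bisquare) regression with bootstrap
    uncertainty, warming-level time sampling, and a synthetic-data generator
    with known ground truth so the whole chain is testable end to end.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ape,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
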