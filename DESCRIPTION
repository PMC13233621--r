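Package: raincascade
Title: Cascading Tipping Dynamics of Forest-Rainfall Feedbacks on
    Moisture-Recycling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a tropical forest basin as a network of locally bistable
    vegetation cells coupled by atmospheric moisture recycling. Computes
    hydrological-year mean annual precipitation (MAP) and maximum cumulative
    water deficit (MCWD) from monthly precipitation and evaporation fields,
    derives per-cell adaptive drought thresholds from a historical window,
    converts grid-to-grid moisture transport into dimensionless couplings on
    the fold-bifurcation normal form, and integrates the interacting system
    under climate drying and deforestation forcing. Reports Monte Carlo
    transition risks, transitioned-area trajectories, and attribution of each
    transition to direct precipitation decline, drought intensification, or
    cascading network effects. Includes a synthetic scenario generator
    (seasonal climate with AR(1) interannual variability and drying trends,
    downwind-biased recycling networks, an advancing deforestation front) so
    the full pipeline runs without external data.
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
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
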