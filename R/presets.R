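#' Named scenario presets
#'
#' Fully specified parameter bundles ordered by drying severity, emulating the
#' shape of emission-scenario forcing: `weak_drying` (trend-free climate
#' variability only), `moderate_drying`, `strong_drying`, and
#' `strong_drying_deforestation` (strong drying plus an eastern-origin
#' clearing front growing from 18% to 35% of the basin over 2020-2050 and held
#' constant after). Drying rates are basin-scale annual-precipitation trends
#' (mm/yr per decade) paired with a deepening dry season (mm/month per
#' decade); the stochastic interannual variability and the recycling network
#' parameters are shared across presets so scenarios differ only in forcing.
#'
#' @param name Preset name.
#' @param seed Integer seed forwarded to the generators.
#' @return A list of class `scenario_preset` with elements `name`, `climate`
#'   ([climate_params()]), `network` ([network_params()]), `deforestation`
#'   (argument list for [make_deforestation()], or `NULL`),
#'   `adaptation_years` and `scenario_years`.
#' @export
scenario_preset <- function(name = c("weak_drying", "moderate_drying",
                                     "strong_drying", "strong_drying_deforestation"),
                            seed = 1L) {
  if (length(name) == 1 && !name %in% c("weak_drying", "moderate_drying",
                                        "strong_drying", "strong_drying_deforestation")) {
    stop_input("unknown preset `%s`.", name)
  }
  name <- match.arg(name)
  trends <- switch(name,
    weak_drying = c(map = 0, dry = 0),
    moderate_drying = c(map = -20, dry = -0.5),
    strong_drying = c(map = -45, dry = -1.5),
    strong_drying_deforestation = c(map = -45, dry = -1.5)
  )
  defor <- if (name == "strong_drying_deforestation") {
    list(start_fraction = 0.18, end_fraction = 0.35, years = 2020:2050,
         origin_edge = "east")
  } else NULL
  structure(list(
    name = name,
    climate = climate_params(
      baseline_map = 2200,
      east_west_gradient = 0.2,
      trend_map_per_decade = trends[["map"]],
      trend_dry_intensity_per_decade = trends[["dry"]],
      trend_start_year = 2015L,
      trend_weight = if (name == "weak_drying") 1 else "east",
      seed = seed
    ),
    network = network_params(seed = seed),
    deforestation = defor,
    adaptation_years = 1950:2014,
    scenario_years = 2015:2100
  ), class = "scenario_preset")
}
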