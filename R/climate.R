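#' Parameters of the synthetic monthly climate generator
#'
#' Bundles the knobs of the synthetic precipitation/evaporation generator that
#' stands in for Earth-system-model forcing. Annual totals follow an AR(1)
#' process around a (optionally drying) baseline; a fixed seasonal profile
#' disaggregates them to months, with a configurable dry season that can
#' deepen over time independently of the annual total.
#'
#' @param baseline_map Basin-mean annual precipitation, mm/yr.
#' @param east_west_gradient Fractional difference in baseline MAP between the
#'   western (wetter) and eastern (drier) edges; 0 gives a uniform basin.
#' @param seasonal_amplitude Reduction of monthly precipitation in dry-season
#'   months relative to the flat annual profile, mm/month (compensated in wet
#'   months so the annual total is unchanged).
#' @param dry_season_months Calendar months forming the dry season.
#' @param ar1_coefficient Lag-1 autocorrelation of annual precipitation
#'   anomalies, in `[0, 1)`.
#' @param anomaly_spatial_corr Fraction of the annual anomaly variance shared
#'   across the whole basin (default 0.25, mimicking basin-coherent, e.g.
#'   ENSO-driven, wet and dry years); the rest is cell-local. Per-cell
#'   variance, and hence the adaptation margins derived from it, do not
#'   depend on this split.
#' @param interannual_sd Stationary standard deviation of annual precipitation
#'   anomalies, mm/yr. The default (550, i.e. 25% of the default baseline)
#'   reproduces the adaptation regime in which losing one standard deviation
#'   of moisture means losing about a quarter of a cell's MAP. Anomalies are
#'   applied multiplicatively (each month scaled by the same annual factor),
#'   so dry months carry proportionally smaller absolute anomalies.
#' @param episodic_share Fraction of the interannual variance carried by a
#'   basin-coherent quasi-biennial episodic mode (alternating drought and wet
#'   episodes, period `episodic_period` years, random phase). Forests are
#'   adapted to these recurrent episodes — they contribute fully to the
#'   historical standard deviation — while decadal averaging cancels them
#'   almost exactly, which is precisely why the analysis works on 10-year
#'   means. Default 0.6.
#' @param episodic_period Period of the episodic mode in years (default 2.5;
#'   with 10-year windows the mode averages out exactly).
#' @param dry_interannual_sd Standard deviation of an additional year-specific
#'   dry-season anomaly, mm/month, applied to dry-season months and
#'   compensated in wet months (so it varies drought intensity without
#'   touching the annual total); emulates years whose dry season is
#'   disproportionately severe.
#' @param trend_map_per_decade Change in annual precipitation per decade,
#'   mm/yr per decade (negative = drying), applied from `trend_start_year`.
#' @param trend_dry_intensity_per_decade Change of dry-season monthly
#'   precipitation per decade, mm/month per decade (negative = deeper dry
#'   season), compensated in wet months so MAP is unaffected.
#' @param trend_start_year First year the trends act; earlier years are
#'   trend-free. `NULL` (default) starts the trend at the first simulated year.
#' @param recovery_start_year Optional year after which the accumulated trend
#'   offsets relax back toward zero at the same absolute rate ("wetting"
#'   scenario); `NULL` disables.
#' @param noise_until Optional calendar year: interannual anomalies are only
#'   generated for hydrological years before it, leaving later years on the
#'   deterministic seasonal-plus-trend climatology. Useful to fit adaptation
#'   on a realistically noisy history while isolating the committed response
#'   to the secular signal; `NULL` (default) keeps noise throughout.
#' @param trend_weight Per-cell multiplier on both trends: a numeric scalar
#'   or per-cell vector, or one of `"east"` / `"west"` for a linear spatial
#'   profile from 1.7 at the named edge through zero to -0.3 at the opposite
#'   edge — drying concentrates at the named edge while the far side of the
#'   basin wets slightly, as large-scale projections typically show.
#' @param evaporation_mean Monthly evaporation, mm/month (held constant).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A list of class `climate_params`.
#' @export
climate_params <- function(baseline_map = 2200,
                           east_west_gradient = 0,
                           seasonal_amplitude = 140,
                           dry_season_months = 6:9,
                           ar1_coefficient = 0,
                           anomaly_spatial_corr = 0.25,
                           interannual_sd = 550,
                           episodic_share = 0.6,
                           episodic_period = 2.5,
                           dry_interannual_sd = 8,
                           trend_map_per_decade = 0,
                           trend_dry_intensity_per_decade = 0,
                           trend_start_year = NULL,
                           recovery_start_year = NULL,
                           noise_until = NULL,
                           trend_weight = 1,
                           evaporation_mean = 100,
                           seed = 1L) {
  if (baseline_map <= 0) stop_input("`baseline_map` must be positive.")
  if (abs(ar1_coefficient) >= 1) stop_input("`ar1_coefficient` must satisfy |phi| < 1.")
  check_fraction(anomaly_spatial_corr, "anomaly_spatial_corr")
  if (interannual_sd < 0) stop_input("`interannual_sd` must be >= 0.")
  check_fraction(episodic_share, "episodic_share")
  if (episodic_period <= 1) stop_input("`episodic_period` must exceed one year.")
  if (evaporation_mean < 0) stop_input("`evaporation_mean` must be >= 0.")
  structure(list(
    baseline_map = baseline_map,
    east_west_gradient = east_west_gradient,
    seasonal_amplitude = seasonal_amplitude,
    dry_season_months = as.integer(dry_season_months),
    ar1_coefficient = ar1_coefficient,
    anomaly_spatial_corr = anomaly_spatial_corr,
    interannual_sd = interannual_sd,
    episodic_share = episodic_share,
    episodic_period = episodic_period,
    dry_interannual_sd = dry_interannual_sd,
    trend_map_per_decade = trend_map_per_decade,
    trend_dry_intensity_per_decade = trend_dry_intensity_per_decade,
    trend_start_year = trend_start_year,
    recovery_start_year = recovery_start_year,
    noise_until = noise_until,
    trend_weight = trend_weight,
    evaporation_mean = evaporation_mean,
    seed = as.integer(seed)
  ), class = "climate_params")
}

#' Simulate monthly precipitation and evaporation fields
#'
#' Generates per-cell monthly precipitation and evaporation series (mm/month)
#' over a range of calendar years. Precipitation combines a per-cell baseline
#' (optionally with an east-west gradient), a fixed seasonal profile, an
#' AR(1) interannual anomaly on annual totals disaggregated uniformly to
#' months, and linear drying trends on the annual total and on dry-season
#' intensity. Negative monthly values are clamped at zero. Evaporation is a
#' constant monthly rate.
#'
#' @param grid Grid tibble from [make_grid()].
#' @param params A [climate_params()] object.
#' @param years Integer vector of consecutive calendar years (>= 1 full year).
#' @return A list with tibbles `precip` and `evap`, each long-format
#'   (`cell_id`, `year`, `month`, `value`).
#' @export
simulate_climate <- function(grid, params, years) {
  if (length(years) < 1) stop_input("`years` must contain at least one year.")
  years <- sort(as.integer(years))
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop_input("`years` must be consecutive calendar years.")
  }
  n <- nrow(grid)
  ny <- length(years)

  # per-cell baseline MAP with optional east-west gradient (west wetter)
  xr <- if (max(grid$x) > min(grid$x)) {
    (grid$x - min(grid$x)) / (max(grid$x) - min(grid$x))
  } else rep(0.5, n)
  base_map <- params$baseline_map * (1 - params$east_west_gradient * (xr - 0.5))

  w <- if (is.character(params$trend_weight)) {
    switch(params$trend_weight,
      east = 2 * xr - 0.3,
      west = 1.7 - 2 * xr,
      stop_input("unknown trend_weight profile `%s`.", params$trend_weight)
    )
  } else rep_len(params$trend_weight, n)
  t0 <- if (is.null(params$trend_start_year)) years[1] else params$trend_start_year

  trend_offset <- function(rate, year) {
    # accumulated offset of a linear per-decade trend, with optional recovery
    elapsed <- pmax(year - t0, 0)
    if (!is.null(params$recovery_start_year)) {
      rc <- params$recovery_start_year
      ramp <- pmin(elapsed, max(rc - t0, 0))
      back <- pmax(year - max(rc, t0), 0)
      off <- rate * ramp / 10 + (-rate) * back / 10
      # never overshoot past zero
      if (rate < 0) pmin(off, 0) else pmax(off, 0)
    } else {
      rate * elapsed / 10
    }
  }
  map_off <- trend_offset(params$trend_map_per_decade, years)        # mm/yr per year
  dry_off <- trend_offset(params$trend_dry_intensity_per_decade, years) # mm/month per year

  # AR(1) anomalies on annual totals plus i.i.d. dry-season anomalies, one
  # chain per cell, in a single deterministic seed stream. Anomalies are
  # indexed by hydrological year (October-September), the accounting unit of
  # the whole analysis, so a "dry year" is dry across one coherent
  # October-September span rather than split across two of them.
  nh <- ny + 1 # hydro years years[1]-1 .. years[ny]
  draws <- with_seed(params$seed, {
    a <- matrix(0, nrow = n, ncol = nh)
    if (params$interannual_sd > 0) {
      ar_sd <- params$interannual_sd * sqrt(1 - params$episodic_share)
      phi <- params$ar1_coefficient
      eps_sd <- ar_sd * sqrt(1 - phi^2)
      ar1_chain <- function(nrows) {
        m <- matrix(0, nrow = nrows, ncol = nh)
        m[, 1] <- rnorm(nrows, sd = ar_sd)
        if (nh > 1) for (j in 2:nh) m[, j] <- phi * m[, j - 1] + rnorm(nrows, sd = eps_sd)
        m
      }
      rho <- params$anomaly_spatial_corr
      shared <- ar1_chain(1)
      local <- ar1_chain(n)
      a <- sqrt(rho) * matrix(shared, nrow = n, ncol = nh, byrow = TRUE) +
        sqrt(1 - rho) * local
      if (params$episodic_share > 0) {
        amp <- params$interannual_sd * sqrt(2 * params$episodic_share)
        phase <- runif(1, 0, 2 * pi)
        epi <- amp * cos(2 * pi * seq_len(nh) / params$episodic_period + phase)
        a <- a + matrix(epi, nrow = n, ncol = nh, byrow = TRUE)
      }
    }
    d <- matrix(0, nrow = n, ncol = nh)
    if (params$dry_interannual_sd > 0) {
      d[] <- rnorm(n * nh, sd = params$dry_interannual_sd)
    }
    list(a = a, d = d)
  })
  anom <- draws$a
  dry_anom <- draws$d
  if (!is.null(params$noise_until)) {
    # hydro-year columns are years[1]-1 .. years[ny]
    hy <- (years[1] - 1L):years[ny]
    quiet <- hy >= params$noise_until
    anom[, quiet] <- 0
    dry_anom[, quiet] <- 0
  }

  dry <- params$dry_season_months
  n_dry <- length(dry)
  n_wet <- 12 - n_dry
  seas <- numeric(12)
  if (n_dry > 0 && n_wet > 0) {
    seas[dry] <- -params$seasonal_amplitude
    seas[-dry] <- params$seasonal_amplitude * n_dry / n_wet
  }

  # cells x (years*12) precipitation matrix; the annual anomaly scales every
  # month of the deterministic profile by the same factor, so its absolute
  # imprint follows the seasonal climatology
  p <- matrix(0, nrow = n, ncol = ny * 12)
  for (j in seq_len(ny)) {
    annual_det <- base_map + w * map_off[j]               # mm/yr per cell
    for (m in 1:12) {
      h <- j + (m >= 10L) # hydro-year column: Oct-Dec belong to the next one
      fac <- ifelse(annual_det > 0, pmax(1 + anom[, h] / annual_det, 0), 1)
      val <- (annual_det / 12 + seas[m]) * fac
      if (m %in% dry) {
        val <- val + w * dry_off[j] + dry_anom[, h]
      } else if (n_wet > 0) {
        val <- val - (w * dry_off[j] + dry_anom[, h]) * n_dry / n_wet
      }
      p[, (j - 1) * 12 + m] <- pmax(val, 0)
    }
  }
  rownames(p) <- grid$cell_id
  attr(p, "years") <- rep(years, each = 12)
  attr(p, "months") <- rep(1:12, times = ny)

  e <- matrix(params$evaporation_mean, nrow = n, ncol = ny * 12,
              dimnames = list(grid$cell_id, NULL))
  attr(e, "years") <- attr(p, "years")
  attr(e, "months") <- attr(p, "months")

  list(precip = matrix_to_field(p), evap = matrix_to_field(e))
}
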