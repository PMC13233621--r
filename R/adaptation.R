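#' Historical adaptation statistics per cell
#'
#' For every cell, computes the mean and standard deviation of hydrological-
#' year MAP and MCWD over the historical adaptation window. The standard
#' deviation is the cell's adaptive capacity: forests that experienced larger
#' hydrological fluctuations are assumed resilient to comparably drier
#' conditions.
#'
#' @param precip,evap Long monthly field tibbles.
#' @param window Integer vector of hydrological-year labels forming the
#'   adaptation window (>= 2 complete years).
#' @param start_month First month of the hydrological year (default October).
#' @param sd_type `"population"` (divide by n; default, treating the window
#'   as the full adaptation history) or `"sample"` (divide by n - 1).
#' @param carry_deficit Passed to [hydro_series()].
#' @return A tibble (`cell_id`, `mu_map`, `delta_map`, `mu_mcwd`,
#'   `delta_mcwd`, `n_years`).
#' @export
fit_adaptation <- function(precip, evap, window, start_month = 10,
                           sd_type = c("population", "sample"),
                           carry_deficit = FALSE) {
  sd_type <- match.arg(sd_type)
  hs <- hydro_series(precip, evap, start_month = start_month,
                     carry_deficit = carry_deficit) |>
    dplyr::filter(.data$hydro_year %in% !!window)
  n_years <- length(unique(hs$hydro_year))
  if (n_years < 2) stop_input("the adaptation window must contain >= 2 complete hydrological years.")
  sdev <- if (sd_type == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else {
    stats::sd
  }
  hs |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      mu_map = mean(.data$map),
      delta_map = sdev(.data$map),
      mu_mcwd = mean(.data$mcwd),
      delta_mcwd = sdev(.data$mcwd),
      n_years = dplyr::n(),
      .groups = "drop"
    )
}

#' Sample per-cell adaptive-capacity multipliers
#'
#' Draws the dimensionless safety-margin multiplier `sigma` for every cell.
#' The default mode draws i.i.d. from a uniform distribution on `bounds`
#' (0.75-1.25 s.d.), representing unresolved variation in adaptive capacity.
#' The scaled modes tie `sigma` to the cell's precipitation percentile rank:
#' `wet_high` gives the wettest cells the upper bound (wet regions more
#' resilient to drying), `wet_low` the reverse. Rank interpolation, rather
#' than raw mm, keeps the scaled modes grid-size invariant.
#'
#' @param grid Grid tibble.
#' @param bounds Numeric `c(low, high)` sigma bounds (default `c(0.75, 1.25)`;
#'   the fixed-threshold robustness mode uses `c(0.50, 1.0)`).
#' @param mode `"uniform_iid"`, `"wet_high"` or `"wet_low"`.
#' @param map_reference Per-cell reference MAP (tibble `cell_id`, `map`, or a
#'   numeric vector in grid order); required for the scaled modes.
#' @param seed Integer seed (only the uniform mode is stochastic).
#' @return A tibble (`cell_id`, `sigma`).
#' @export
sample_sigma <- function(grid, bounds = c(0.75, 1.25),
                         mode = c("uniform_iid", "wet_high", "wet_low"),
                         map_reference = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (bounds[1] > bounds[2]) stop_input("sigma bounds must satisfy low <= high.")
  n <- nrow(grid)
  sigma <- if (mode == "uniform_iid") {
    with_seed(seed, runif(n, bounds[1], bounds[2]))
  } else {
    if (is.null(map_reference)) stop_input("scaled sigma modes need `map_reference`.")
    mr <- if (is.data.frame(map_reference)) {
      map_reference$map[match(grid$cell_id, map_reference$cell_id)]
    } else map_reference
    if (anyNA(mr)) stop_input("`map_reference` misses cells of the grid.")
    r <- if (n == 1) 0.5 else (rank(mr, ties.method = "average") - 1) / (n - 1)
    if (mode == "wet_low") r <- 1 - r
    bounds[1] + r * (bounds[2] - bounds[1])
  }
  tibble::tibble(cell_id = grid$cell_id, sigma = sigma)
}

#' Critical MAP and MCWD thresholds from adaptation statistics
#'
#' Each cell tips when its windowed MAP falls `sigma` standard deviations
#' below its historical mean (`map_crit = mu_map - sigma * delta_map`) or its
#' windowed MCWD rises `sigma` standard deviations above it
#' (`mcwd_crit = mu_mcwd + sigma * delta_mcwd`). Cells with a degenerate
#' margin (`sigma * delta = 0`) get `crit = mu` and are flagged
#' non-tippable with a warning.
#'
#' @param profile Tibble from [fit_adaptation()].
#' @param sigma Tibble (`cell_id`, `sigma`) from [sample_sigma()], or a
#'   scalar applied to every cell.
#' @return The profile with columns `sigma`, `map_crit`, `mcwd_crit` and
#'   `tippable` added.
#' @export
compute_thresholds <- function(profile, sigma) {
  if (!is.data.frame(sigma)) {
    sigma <- tibble::tibble(cell_id = profile$cell_id, sigma = sigma)
  }
  out <- profile |>
    dplyr::inner_join(sigma, by = "cell_id") |>
    dplyr::mutate(
      map_crit = .data$mu_map - .data$sigma * .data$delta_map,
      mcwd_crit = .data$mu_mcwd + .data$sigma * .data$delta_mcwd,
      tippable = .data$sigma * .data$delta_map > 0 & .data$sigma * .data$delta_mcwd > 0
    )
  if (any(!out$tippable)) {
    rlang::warn(sprintf("%d cell(s) have a degenerate adaptation margin and are flagged non-tippable.",
                        sum(!out$tippable)))
  }
  out
}

#' Forbidden-to-tip guard mask from absolute thresholds
#'
#' Robustness mode mixing adaptive thresholds with hard-wired safe
#' boundaries: cells whose decadal MAP exceeds `map_guard` and (or, with
#' `combine = "or"`) whose decadal MCWD stays below `mcwd_guard` are
#' forbidden to tip, and hence never initiate or relay cascades.
#'
#' @param decadal_map,decadal_mcwd Per-cell windowed MAP and MCWD, mm/yr.
#' @param map_guard MAP safe boundary, mm/yr (default 1850).
#' @param mcwd_guard MCWD safe boundary, mm/yr (default 350).
#' @param combine `"and"` (default): both conditions must hold; `"or"`:
#'   either suffices.
#' @return Logical vector, `TRUE` for guarded cells.
#' @export
guard_mask <- function(decadal_map, decadal_mcwd, map_guard = 1850,
                       mcwd_guard = 350, combine = c("and", "or")) {
  combine <- match.arg(combine)
  a <- decadal_map > map_guard
  b <- decadal_mcwd < mcwd_guard
  if (combine == "and") a & b else a | b
}
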