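#' Label complete hydrological years in a monthly field
#'
#' Hydrological years run from October of one calendar year to September of
#' the next (configurable), aligning the accounting year with the wet/dry
#' season cycle. Each year is labelled by the calendar year of its starting
#' month. Leading and trailing partial years are dropped.
#'
#' @param field Long monthly field tibble (`cell_id`, `year`, `month`,
#'   `value`).
#' @param start_month First month of the hydrological year (default 10,
#'   October; 1 gives calendar years).
#' @return The field restricted to complete hydrological years, with a
#'   `hydro_year` column added and rows ordered by cell, hydrological year and
#'   position within the year.
#' @export
hydrological_years <- function(field, start_month = 10) {
  if (!start_month %in% 1:12) stop_input("`start_month` must be in 1..12.")
  out <- field |>
    dplyr::mutate(
      hydro_year = ifelse(.data$month >= start_month, .data$year, .data$year - 1L),
      .month_pos = (.data$month - start_month) %% 12L
    )
  complete <- out |>
    dplyr::distinct(.data$hydro_year, .data$month) |>
    dplyr::count(.data$hydro_year) |>
    dplyr::filter(.data$n == 12L) |>
    dplyr::pull(.data$hydro_year)
  if (length(complete) == 0) {
    rlang::warn("no complete hydrological year in the field; returning empty result.")
  }
  out |>
    dplyr::filter(.data$hydro_year %in% complete) |>
    dplyr::arrange(.data$cell_id, .data$hydro_year, .data$.month_pos) |>
    dplyr::select(-".month_pos")
}

#' Mean annual precipitation of one hydrological year
#'
#' MAP is simply the sum of the twelve monthly precipitation values of the
#' hydrological year, in mm/yr.
#'
#' @param p Numeric vector of 12 monthly precipitation values (mm/month).
#' @return MAP in mm/yr.
#' @export
#' @examples
#' compute_map(rep(100, 12))
compute_map <- function(p) {
  if (length(p) != 12) stop_input("a hydrological-year block must have 12 months.")
  if (any(p < 0)) stop_input("precipitation must be non-negative.")
  sum(p)
}

#' Maximum cumulative water deficit of one hydrological year
#'
#' Runs the cumulative water deficit recursion over the twelve months of a
#' hydrological year: `CWD_m = min(0, CWD_{m-1} + P_m - E_m)` with
#' `CWD_0 = 0` (or a carried-over deficit), i.e. the running water balance is
#' capped at zero whenever surpluses would make it positive. MCWD is the
#' absolute value of the minimum CWD reached, a measure of dry-season
#' intensity in mm/yr.
#'
#' @param p,e Numeric vectors of 12 monthly precipitation and evaporation
#'   values (mm/month).
#' @param cwd0 Initial deficit (<= 0); non-zero only in the cross-year
#'   carrying variant.
#' @return MCWD (>= 0), with the final CWD attached as attribute `cwd_final`
#'   for chaining across years.
#' @export
#' @examples
#' compute_mcwd(rep(100, 12), rep(110, 12)) # constant deficit: 120
compute_mcwd <- function(p, e, cwd0 = 0) {
  if (length(p) != 12 || length(e) != 12) {
    stop_input("hydrological-year blocks must have 12 months.")
  }
  cwd <- cwd0
  lowest <- 0
  for (m in 1:12) {
    cwd <- min(0, cwd + p[m] - e[m])
    lowest <- min(lowest, cwd)
  }
  structure(abs(lowest), cwd_final = cwd)
}

# Vectorised MCWD over a cells x 12 deficit matrix (P - E), optionally with a
# per-cell initial deficit; returns mcwd vector and final cwd.
mcwd_blocks <- function(d, cwd0 = NULL) {
  n <- nrow(d)
  cwd <- if (is.null(cwd0)) numeric(n) else cwd0
  lowest <- numeric(n)
  for (m in seq_len(ncol(d))) {
    cwd <- pmin(0, cwd + d[, m])
    lowest <- pmin(lowest, cwd)
  }
  list(mcwd = abs(lowest), cwd_final = cwd)
}

#' Per-cell MAP and MCWD series over hydrological years
#'
#' Computes, for every cell and every complete hydrological year, the mean
#' annual precipitation (MAP) and the maximum cumulative water deficit
#' (MCWD).
#'
#' @param precip,evap Long monthly field tibbles (`cell_id`, `year`, `month`,
#'   `value`), on the same cells and months.
#' @param start_month First month of the hydrological year (default October).
#' @param carry_deficit If `TRUE`, the cumulative water deficit is carried
#'   across hydrological-year boundaries instead of resetting to zero at each
#'   October (the default, which treats each hydrological year as an
#'   independent 12-month window).
#' @return A tibble (`cell_id`, `hydro_year`, `map`, `mcwd`).
#' @export
hydro_series <- function(precip, evap, start_month = 10, carry_deficit = FALSE) {
  ph <- hydrological_years(precip, start_month)
  eh <- hydrological_years(evap, start_month)
  if (nrow(ph) == 0) {
    return(tibble::tibble(cell_id = integer(), hydro_year = integer(),
                          map = numeric(), mcwd = numeric()))
  }
  if (nrow(ph) != nrow(eh)) stop_input("precipitation and evaporation fields are not aligned.")
  if (any(ph$value < 0)) stop_input("precipitation must be non-negative.")

  cells <- sort(unique(ph$cell_id))
  hys <- sort(unique(ph$hydro_year))
  # cells x (years*12) matrices in hydro-year month order
  ord <- order(match(ph$cell_id, cells))
  pm <- matrix(ph$value[ord], nrow = length(cells), byrow = TRUE)
  em <- matrix(eh$value[order(match(eh$cell_id, cells))], nrow = length(cells), byrow = TRUE)
  d <- pm - em

  maps <- sapply(seq_along(hys), function(j) rowSums(pm[, (j - 1) * 12 + 1:12, drop = FALSE]))
  mc <- matrix(0, nrow = length(cells), ncol = length(hys))
  cwd0 <- NULL
  for (j in seq_along(hys)) {
    res <- mcwd_blocks(d[, (j - 1) * 12 + 1:12, drop = FALSE],
                       cwd0 = if (carry_deficit) cwd0 else NULL)
    mc[, j] <- res$mcwd
    cwd0 <- res$cwd_final
  }
  tibble::tibble(
    cell_id = rep(cells, times = length(hys)),
    hydro_year = rep(hys, each = length(cells)),
    map = as.vector(matrix(maps, nrow = length(cells))),
    mcwd = as.vector(mc)
  ) |>
    dplyr::arrange(.data$cell_id, .data$hydro_year)
}

#' Running decadal means of annual hydrological metrics
#'
#' Applies a running mean over hydrological years to smooth out single
#' particularly wet or dry years; the committed-transition analysis evaluates
#' these windowed values rather than single years. A window of years
#' `y..y+w-1` is labelled by `y + floor(w/2)` (so the 2021-2030 window is
#' labelled 2026). Windows that are incomplete are not emitted.
#'
#' @param series Tibble with a `hydro_year` column, optional `cell_id`, and
#'   numeric metric columns (e.g. from [hydro_series()]).
#' @param window Window length in years (default 10).
#' @return A tibble with the same metric columns holding windowed means and
#'   `hydro_year` holding the window labels.
#' @export
windowed_means <- function(series, window = 10) {
  if (window < 1 || window != round(window)) stop_input("`window` must be a positive integer.")
  metric_cols <- setdiff(names(series)[vapply(series, is.numeric, logical(1))],
                         c("cell_id", "hydro_year"))
  run_mean <- function(x, w) {
    if (length(x) < w) return(numeric(0))
    cs <- cumsum(c(0, x))
    (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
  }
  one_group <- function(df) {
    df <- dplyr::arrange(df, .data$hydro_year)
    yrs <- df$hydro_year
    if (length(yrs) > 1 && any(diff(yrs) != 1L)) {
      stop_input("hydro years must be consecutive for windowed means.")
    }
    if (length(yrs) < window) {
      return(df[0, c("hydro_year", metric_cols)])
    }
    out <- tibble::tibble(hydro_year = yrs[seq_len(length(yrs) - window + 1)] + floor(window / 2))
    for (cc in metric_cols) out[[cc]] <- run_mean(df[[cc]], window)
    out
  }
  grouped <- "cell_id" %in% names(series)
  res <- if (grouped) {
    series |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::group_modify(~ one_group(.x)) |>
      dplyr::ungroup()
  } else {
    one_group(series)
  }
  if (nrow(res) == 0) rlang::warn("window longer than the series; returning empty result.")
  res
}

#' Replace evaporation by a constant monthly value
#'
#' Robustness transform substituting measured (water-limited) evaporation by a
#' constant rate, a conservative stand-in for potential evapotranspiration
#' when assessing drought intensity.
#'
#' @param evap Long monthly evaporation field tibble.
#' @param value Constant evaporation, mm/month (default 100).
#' @return The field with every monthly value replaced by `value`.
#' @export
constant_et_transform <- function(evap, value = 100) {
  if (value < 0) stop_input("`value` must be >= 0.")
  dplyr::mutate(evap, value = !!value)
}
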