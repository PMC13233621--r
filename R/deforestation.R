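#' Generate a deforestation-front scenario
#'
#' Produces per-cell, per-year deforested fractions in which a clearing front
#' advances from one edge of the basin (a logistic profile in distance from
#' that edge) while the basin-wide cleared-area fraction ramps linearly from
#' `start_fraction` to `end_fraction` over `years`. Per-cell fractions are
#' non-decreasing in time; querying beyond the last year holds the final
#' state constant.
#'
#' @param grid Grid tibble from [make_grid()].
#' @param start_fraction,end_fraction Basin-wide cleared-area fractions at the
#'   first and last year (`0 <= start <= end <= 1`).
#' @param years Integer vector of consecutive calendar years of the ramp.
#' @param origin_edge Edge the front advances from: `"east"`, `"west"`,
#'   `"north"`, `"south"` or `"southeast"`.
#' @param front_width Logistic width of the front, grid units.
#' @return A tibble of class `landuse_series` (`cell_id`, `year`, `fraction`).
#' @export
make_deforestation <- function(grid, start_fraction, end_fraction, years,
                               origin_edge = c("east", "west", "north", "south", "southeast"),
                               front_width = 1) {
  origin_edge <- match.arg(origin_edge)
  check_fraction(c(start_fraction, end_fraction), "fractions")
  if (end_fraction < start_fraction) stop_input("`end_fraction` must be >= `start_fraction`.")
  years <- sort(as.integer(years))

  d <- switch(origin_edge,
    east = max(grid$x) - grid$x,
    west = grid$x - min(grid$x),
    north = max(grid$y) - grid$y,
    south = grid$y - min(grid$y),
    southeast = sqrt((max(grid$x) - grid$x)^2 + (grid$y - min(grid$y))^2)
  )
  area_w <- grid$area / sum(grid$area)

  front_fracs <- function(target) {
    if (target <= 0) return(rep(0, nrow(grid)))
    if (target >= 1) return(rep(1, nrow(grid)))
    mean_frac <- function(s) sum(area_w * stats::plogis((s - d) / front_width)) - target
    lo <- min(d) - 50 * front_width
    hi <- max(d) + 50 * front_width
    s <- uniroot(mean_frac, c(lo, hi), tol = 1e-12)$root
    stats::plogis((s - d) / front_width)
  }

  targets <- if (length(years) == 1) {
    end_fraction
  } else {
    start_fraction + (end_fraction - start_fraction) *
      (years - years[1]) / (years[length(years)] - years[1])
  }
  out <- purrr::map2_dfr(years, targets, function(y, tg) {
    tibble::tibble(cell_id = grid$cell_id, year = y, fraction = front_fracs(tg))
  }) |>
    dplyr::arrange(.data$cell_id, .data$year)
  structure(out, class = c("landuse_series", class(out)))
}

#' Deforested fractions in force at a given year
#'
#' Looks up the per-cell deforested fractions of a [make_deforestation()]
#' series at a year, holding the series constant outside its range (zero-ish
#' start state before, final state after).
#'
#' @param landuse A `landuse_series` tibble, or `NULL` for no deforestation.
#' @param year Calendar year.
#' @param grid Grid tibble (used to return zeros when `landuse` is `NULL`).
#' @return A tibble (`cell_id`, `fraction`).
#' @export
landuse_at <- function(landuse, year, grid = NULL) {
  if (is.null(landuse)) {
    if (is.null(grid)) stop_input("need `grid` when `landuse` is NULL.")
    return(tibble::tibble(cell_id = grid$cell_id, fraction = 0))
  }
  yrs <- sort(unique(landuse$year))
  y <- min(max(year, yrs[1]), yrs[length(yrs)])
  landuse |>
    dplyr::filter(.data$year == !!y) |>
    dplyr::select("cell_id", "fraction")
}
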