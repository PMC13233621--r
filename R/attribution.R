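#' Attribute transitions to their cause
#'
#' Labels every cell of a snapshot: deforested cells are `"deforested"`;
#' other transitioned cells are `"map"` if their MAP forcing alone exceeds
#' the critical forcing, `"mcwd"` if their MCWD forcing does (the larger
#' component wins when both exceed it), and `"network"` otherwise — i.e. the
#' cell tipped only because upwind transitions removed its stabilizing
#' moisture inputs. Single-driver modes only attribute to their driver.
#' A transitioned cell with all components stabilizing and no tipped
#' in-neighbour is flagged as an inconsistency with a warning.
#'
#' @param snapshot A `tipping_snapshot` tibble.
#' @param coupling Optional `coupling_matrix` used for the consistency check.
#' @param config A [model_config()].
#' @return The snapshot with a `reason` column added (factor-like character).
#' @export
attribute_transitions <- function(snapshot, coupling = NULL, config = model_config()) {
  cs <- c_star()
  a <- if (config$driver_mode == "mcwd_only") rep(-Inf, nrow(snapshot)) else snapshot$c_map
  b <- if (config$driver_mode == "map_only") rep(-Inf, nrow(snapshot)) else snapshot$c_mcwd
  reason <- rep("none", nrow(snapshot))
  tr <- snapshot$transitioned
  reason[tr] <- "network"
  reason[tr & a >= cs & a >= b] <- "map"
  reason[tr & b >= cs & b > a] <- "mcwd"
  reason[snapshot$forced] <- "deforested"
  snapshot$reason <- reason

  net <- which(reason == "network")
  if (length(net) > 0 && !is.null(coupling)) {
    tipped_ids <- snapshot$cell_id[tr]
    has_in <- snapshot$cell_id[net] %in%
      coupling$target[coupling$source %in% tipped_ids & coupling$r > 0]
    bad <- !has_in & snapshot$c_crit[net] <= 0
    if (any(bad)) {
      rlang::warn(sprintf("%d transitioned cell(s) have stabilizing forcing and no tipped in-neighbour.",
                          sum(bad)))
    }
  }
  snapshot
}

#' Shares of the three transition causes
#'
#' Summarises the attributed reasons of one or more snapshots as counts and
#' percentage shares. Deforested cells are excluded from the three-way split
#' (they are reported separately in area terms), so the `map`, `mcwd` and
#' `network` shares sum to 100% of attributed transitions.
#'
#' @param snapshot A `tipping_snapshot` tibble, or any tibble with a
#'   `reason` column (e.g. pooled ensemble states).
#' @return A tibble (`reason`, `n`, `share_pct`) over the reasons
#'   `map`, `mcwd`, `network` (always all three rows, zero counts included).
#' @export
attribution_shares <- function(snapshot) {
  counts <- snapshot |>
    dplyr::filter(.data$reason %in% c("map", "mcwd", "network")) |>
    dplyr::count(.data$reason)
  out <- tibble::tibble(reason = c("map", "mcwd", "network")) |>
    dplyr::left_join(counts, by = "reason") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  total <- sum(out$n)
  out$share_pct <- if (total > 0) 100 * out$n / total else rep(0, 3)
  out
}

#' MAP-MCWD risk plane
#'
#' Tabulates scenario snapshots in the plane of basin-mean windowed MAP and
#' MCWD and flags high-risk conditions: any snapshot whose transitioned area
#' reaches at least `threshold_pct` of the basin (inclusive at the boundary).
#'
#' @param results Tibble with columns `map`, `mcwd` (basin-mean windowed
#'   values, mm/yr) and `area_pct` (transitioned area, % of basin); extra
#'   columns are carried through.
#' @param threshold_pct High-risk threshold on transitioned area (default
#'   10%).
#' @return The table with a logical `high_risk` column added.
#' @export
risk_plane <- function(results, threshold_pct = 10) {
  if (nrow(results) < 1) stop_input("`results` must contain at least one snapshot.")
  dplyr::mutate(results, high_risk = .data$area_pct >= !!threshold_pct)
}
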