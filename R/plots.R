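#' Map a snapshot's steady states on the grid
#'
#' @param object A `tipping_snapshot`.
#' @param grid Grid tibble supplying cell coordinates.
#' @param ... Unused.
#' @return A ggplot: cells tiled by transition cause.
#' @method autoplot tipping_snapshot
#' @export
autoplot.tipping_snapshot <- function(object, grid, ...) {
  df <- dplyr::inner_join(tibble::as_tibble(object),
                          dplyr::select(grid, "cell_id", "x", "y"),
                          by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$reason)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      none = "darkgreen", map = "goldenrod", mcwd = "orangered",
      network = "purple", deforested = "grey30"), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "state / cause", x = NULL, y = NULL)
}

#' Transition-risk map
#'
#' @param ensemble A `tipping_ensemble`.
#' @param grid Grid tibble supplying cell coordinates.
#' @param snapshot Snapshot label to map (default: the last).
#' @return A ggplot: per-cell risk (fraction of members transitioned).
#' @export
plot_risk_map <- function(ensemble, grid, snapshot = NULL) {
  labs <- unique(ensemble$risk$snapshot)
  if (is.null(snapshot)) snapshot <- labs[length(labs)]
  df <- ensemble$risk |>
    dplyr::filter(.data$snapshot == !!snapshot) |>
    dplyr::inner_join(dplyr::select(grid, "cell_id", "x", "y"), by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$risk)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkgreen", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Transition risk,", snapshot),
                  fill = "risk", x = NULL, y = NULL)
}

#' Transitioned-area trajectory
#'
#' @param ensemble A `tipping_ensemble`.
#' @return A ggplot: transitioned area (% of basin) per snapshot, the ribbon
#'   spanning one across-member standard deviation, with the deforested area
#'   dashed.
#' @export
plot_area_series <- function(ensemble) {
  df <- ensemble$area |>
    dplyr::mutate(snapshot = factor(.data$snapshot, levels = .data$snapshot),
                  idx = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$idx, .data$area_mean_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$area_mean_pct - .data$area_sd_pct,
      ymax = .data$area_mean_pct + .data$area_sd_pct), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$deforested_pct), linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = df$idx, labels = df$snapshot) +
    ggplot2::labs(x = NULL, y = "transitioned area (% of basin)")
}

#' MAP-MCWD risk plane
#'
#' @param ensemble A `tipping_ensemble`, or a risk-plane tibble from
#'   [risk_plane()].
#' @return A ggplot: snapshots in the plane of basin-mean windowed MAP and
#'   MCWD, point size the transitioned area, high-risk points ringed.
#' @export
plot_risk_plane <- function(ensemble) {
  df <- if (inherits(ensemble, "tipping_ensemble")) ensemble$plane else ensemble
  ggplot2::ggplot(df, ggplot2::aes(.data$map, .data$mcwd, size = .data$area_pct,
                                   colour = .data$high_risk)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "red")) +
    ggplot2::labs(x = "basin-mean MAP (mm/yr)", y = "basin-mean MCWD (mm/yr)",
                  size = "transitioned %", colour = "high risk")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
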