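#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tipping snapshot
#'
#' Returns the per-cell results of one committed-transition snapshot as a
#' plain tibble.
#'
#' @param x A `tipping_snapshot`.
#' @param ... Unused.
#' @return A tibble, one row per cell.
#' @method tidy tipping_snapshot
#' @export
tidy.tipping_snapshot <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a tipping snapshot
#'
#' @param x A `tipping_snapshot`.
#' @param ... Unused.
#' @return A tibble with one row: cell counts, transitioned share and cause
#'   counts, plus the solver's convergence diagnostics.
#' @method glance tipping_snapshot
#' @export
glance.tipping_snapshot <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_transitioned = sum(x$transitioned),
    pct_transitioned = 100 * mean(x$transitioned),
    n_map = sum(x$reason == "map"),
    n_mcwd = sum(x$reason == "mcwd"),
    n_network = sum(x$reason == "network"),
    n_deforested = sum(x$reason == "deforested"),
    converged = isTRUE(attr(x, "converged")),
    residual = attr(x, "residual")
  )
}

#' Tidy a tipping ensemble
#'
#' @param x A `tipping_ensemble`.
#' @param ... Unused.
#' @return The per-cell, per-snapshot transition risk tibble.
#' @method tidy tipping_ensemble
#' @export
tidy.tipping_ensemble <- function(x, ...) x$risk

#' Per-snapshot summary of a tipping ensemble
#'
#' @param x A `tipping_ensemble`.
#' @param ... Unused.
#' @return A tibble, one row per snapshot: transitioned-area mean and s.d.
#'   (% of basin), deforested area, basin-mean windowed MAP and MCWD and the
#'   high-risk flag.
#' @method glance tipping_ensemble
#' @export
glance.tipping_ensemble <- function(x, ...) {
  dplyr::left_join(x$area,
                   dplyr::select(x$plane, "snapshot", "map", "mcwd", "high_risk"),
                   by = "snapshot")
}

#' @export
print.tipping_ensemble <- function(x, ...) {
  cat("<tipping_ensemble>", length(unique(x$area$snapshot)), "snapshots x",
      x$config$n_members, "members\n")
  print(glance(x))
  invisible(x)
}
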