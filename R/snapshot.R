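#' Run one committed-transition snapshot
#'
#' Evaluates the committed equilibrium for one snapshot of climatic
#' conditions: builds the per-cell forcing from windowed MAP/MCWD, the
#' coupling matrix from the link effects, applies deforestation (permanently
#' lost source moisture becomes a static forcing on targets, the surviving
#' share participates in the state-dependent coupling, and cells at least
#' half cleared are held in the transitioned state), integrates the network
#' to steady state and attributes each transition to its cause.
#'
#' @param hydro Tibble (`cell_id`, `map`, `mcwd`) of windowed values, mm/yr.
#' @param effects Link effects from [link_effects()].
#' @param profile Threshold profile from [compute_thresholds()].
#' @param landuse Per-cell deforested fractions (tibble `cell_id`,
#'   `fraction`), or `NULL`.
#' @param config A [model_config()].
#' @return A `tipping_snapshot` tibble with columns `cell_id`, `x_final`,
#'   `transitioned`, `c_map`, `c_mcwd`, `c_crit`, `forced`, `guarded`,
#'   `deforested_fraction` and `reason` (`"map"`, `"mcwd"`, `"network"`,
#'   `"deforested"` or `"none"`).
#' @export
run_snapshot <- function(hydro, effects, profile, landuse = NULL,
                         config = model_config()) {
  forcing <- forcing_components(hydro, profile, config)
  cells <- forcing$cell_id

  guarded <- NULL
  if (isTRUE(config$guard)) {
    h <- hydro[match(cells, hydro$cell_id), ]
    guarded <- guard_mask(h$map, h$mcwd, config$guard_map, config$guard_mcwd,
                          config$guard_combine)
  }

  coupling <- coupling_matrix(effects, profile, forcing, config)

  f <- rep(0, length(cells))
  if (!is.null(landuse)) {
    lu <- landuse_vector(landuse)
    idx <- match(as.character(cells), names(lu))
    f <- ifelse(is.na(idx), 0, lu[idx])
    check_fraction(f, "landuse fractions")
  }
  static <- NULL
  if (any(f > 0) && nrow(coupling) > 0) {
    loss <- f[match(coupling$source, cells)] * (1 - config$retention)
    removed <- coupling$r * loss
    agg <- rowsum(removed, match(coupling$target, cells))
    static <- rep(0, length(cells))
    static[as.integer(rownames(agg))] <- agg[, 1]
    coupling$r <- coupling$r * (1 - loss)
  }
  forced <- f >= 0.5

  snap <- integrate_network(forcing, coupling, config = config,
                            forced_tipped = forced, guarded = guarded,
                            static_forcing = static)
  snap$deforested_fraction <- f
  attribute_transitions(snap, coupling = coupling, config = config)
}
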