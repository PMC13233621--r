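#' Dimensionless coupling matrix from link effects
#'
#' Converts each moisture link's hydrological effects into a dimensionless
#' coupling on the target's fold normal form. The MAP compartment relates the
#' annually delivered moisture to the target's adaptive range
#' (`r_map = c* * delta_map / (mu_map - map_crit)` in the default monotone
#' form, so a link carrying the full adaptive range is exactly
#' tipping-equivalent); the MCWD compartment is
#' `c* * delta_mcwd / (mcwd_crit - mu_mcwd)`. The two are combined with the
#' same capped algebra as the forcing components; single-driver modes use
#' only their compartment. The literal reciprocal MAP form is available for
#' comparison runs.
#'
#' @param effects Link-effects tibble from [link_effects()] (`source`,
#'   `target`, `delta_map`, `delta_mcwd`).
#' @param profile Threshold profile from [compute_thresholds()].
#' @param forcing Per-cell forcing tibble from [forcing_components()]
#'   (used for bookkeeping of which component dominates at the target).
#' @param config A [model_config()].
#' @return A tibble of class `coupling_matrix` (`source`, `target`, `r`);
#'   links onto non-tippable targets are dropped.
#' @export
coupling_matrix <- function(effects, profile, forcing = NULL, config = model_config()) {
  if (any(effects$delta_map < 0)) stop_input("`delta_map` must be non-negative.")
  if (any(effects$delta_mcwd < 0)) stop_input("`delta_mcwd` must be non-negative.")
  df <- effects |>
    dplyr::inner_join(
      dplyr::select(profile, "cell_id", "mu_map", "map_crit", "mu_mcwd",
                    "mcwd_crit", "tippable"),
      by = c(target = "cell_id")
    ) |>
    dplyr::filter(.data$tippable, .data$source != .data$target)
  r_map <- if (config$map_form == "monotone_ramp") {
    c_star() * df$delta_map / (df$mu_map - df$map_crit)
  } else {
    c_star() * (df$map_crit - df$mu_map) / ifelse(df$delta_map > 0, df$delta_map, Inf)
  }
  r_mcwd <- c_star() * df$delta_mcwd / (df$mcwd_crit - df$mu_mcwd)
  r <- switch(config$driver_mode,
    both = combine_components(r_map, r_mcwd),
    map_only = r_map,
    mcwd_only = r_mcwd
  )
  out <- tibble::tibble(source = df$source, target = df$target, r = r) |>
    dplyr::filter(.data$r != 0)
  structure(out, class = c("coupling_matrix", class(out)))
}

#' Classify steady states as transitioned or forest
#'
#' @param x Per-cell steady-state values.
#' @param threshold Dimensionless cut (default 0; the equilibria sit near -1
#'   and +1, so any value strictly above the cut counts as transitioned).
#' @return Logical vector.
#' @export
classify_states <- function(x, threshold = 0) x > threshold

# shared argument marshalling for the integrator and the cascade oracle
dyn_inputs <- function(forcing, coupling, forced_tipped, guarded, static_forcing) {
  cells <- forcing$cell_id
  n <- length(cells)
  as_mask <- function(m) {
    if (is.null(m)) return(rep(FALSE, n))
    if (is.logical(m)) { stopifnot(length(m) == n); return(m) }
    cells %in% m # vector of cell ids
  }
  forced <- as_mask(forced_tipped)
  guard <- as_mask(guarded) | !forcing$tippable
  c_eff <- forcing$c_crit + (if (is.null(static_forcing)) 0 else static_forcing)
  edges <- if (is.null(coupling) || nrow(coupling) == 0) {
    list(src = integer(0), tgt = integer(0), r = numeric(0))
  } else {
    keep <- coupling$source %in% cells & coupling$target %in% cells
    list(src = match(coupling$source[keep], cells) - 1L,
         tgt = match(coupling$target[keep], cells) - 1L,
         r = coupling$r[keep])
  }
  list(cells = cells, n = n, forced = forced, guard = guard,
       c_eff = c_eff, edges = edges)
}

#' Integrate the coupled tipping network to steady state
#'
#' Integrates `dx_i/dt = -x_i^3 + x_i + c_i + sum_k R_ki w(x_k)` with
#' fixed-step RK4 from the forest state (or a supplied initial condition)
#' until the residual falls below `config$tol` or `t_max` is reached. The
#' coupling weight is `w(x) = (x+1)/2` (zero baseline, default) or `x/2`
#' (literal), with the source state saturated to `[-1, 1]` so a transitioned
#' source never removes more than its full link. Deforested cells are held at +1, guarded and non-tippable
#' cells at the forest state.
#'
#' @param forcing Tibble from [forcing_components()].
#' @param coupling Tibble from [coupling_matrix()] (or `NULL` for an
#'   uncoupled run).
#' @param init Per-cell initial states (default -1 everywhere).
#' @param config A [model_config()].
#' @param forced_tipped Cells held at +1: a logical vector over cells or a
#'   vector of cell ids (e.g. deforested cells).
#' @param guarded Cells forbidden to tip, same conventions.
#' @param static_forcing Optional per-cell additive forcing (e.g. the
#'   permanently lost moisture of partially deforested sources).
#' @return A tibble of class `tipping_snapshot` (`cell_id`, `x_final`,
#'   `transitioned`, `c_map`, `c_mcwd`, `c_crit`, `forced`, `guarded`), with
#'   attributes `converged`, `t_end` and `residual`. Non-convergence at
#'   `t_max` triggers a warning, never a silent result.
#' @export
integrate_network <- function(forcing, coupling = NULL, init = NULL,
                              config = model_config(), forced_tipped = NULL,
                              guarded = NULL, static_forcing = NULL) {
  inp <- dyn_inputs(forcing, coupling, forced_tipped, guarded, static_forcing)
  x0 <- if (is.null(init)) rep(-1, inp$n) else rep_len(init, inp$n)
  res <- rk4_steady_state(inp$c_eff, inp$edges$src, inp$edges$tgt, inp$edges$r,
                          x0, inp$forced, inp$guard,
                          config$dt, config$t_max, config$tol,
                          if (config$coupling_baseline == "zero_baseline") 0L else 1L)
  if (!res$converged) {
    rlang::warn(sprintf("integration did not converge by t_max = %g (residual %.3g).",
                        config$t_max, res$residual))
  }
  out <- tibble::tibble(
    cell_id = inp$cells,
    x_final = res$x,
    transitioned = classify_states(res$x, config$transition_threshold) | inp$forced,
    c_map = forcing$c_map,
    c_mcwd = forcing$c_mcwd,
    c_crit = forcing$c_crit,
    forced = inp$forced,
    guarded = inp$guard
  )
  structure(out, class = c("tipping_snapshot", class(out)),
            converged = res$converged, t_end = res$t_end,
            residual = res$residual, config = config)
}

#' Discrete cascade oracle
#'
#' Fixed-point iteration mirroring the zero-baseline ODE dynamics without
#' integrating: starting from the seed set, any cell whose effective forcing
#' (its own forcing plus the couplings from already-tipped sources) strictly
#' exceeds the critical forcing `sqrt(4/27)` tips, until no cell changes.
#' Terminates in at most N passes and is monotone in the seed set and in the
#' couplings. Used as an independent check on the ODE steady states.
#'
#' @inheritParams integrate_network
#' @param seed_tipped Initially tipped cells (cell ids or logical mask).
#' @return Integer vector of tipped cell ids, with attribute `margin`: the
#'   minimum distance of any cell's effective forcing from the critical
#'   forcing across all passes of the iteration.
#' @export
discrete_cascade <- function(forcing, coupling = NULL, seed_tipped = NULL,
                             guarded = NULL, static_forcing = NULL) {
  inp <- dyn_inputs(forcing, coupling, seed_tipped, guarded, static_forcing)
  tipped <- inp$forced & !inp$guard
  margin <- Inf
  cs <- c_star()
  repeat {
    eff <- inp$c_eff
    if (length(inp$edges$r) > 0 && any(tipped)) {
      on_edges <- tipped[inp$edges$src + 1L]
      if (any(on_edges)) {
        add <- rowsum(inp$edges$r[on_edges], inp$edges$tgt[on_edges] + 1L)
        eff[as.integer(rownames(add))] <- eff[as.integer(rownames(add))] + add[, 1]
      }
    }
    margin <- min(margin, min(abs(eff[!inp$guard] - cs), Inf))
    new_tipped <- (tipped | (eff > cs)) & !inp$guard
    new_tipped <- new_tipped | inp$forced
    if (all(new_tipped == tipped)) break
    tipped <- new_tipped
  }
  structure(inp$cells[tipped], margin = margin)
}
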