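#' Model configuration
#'
#' Collects the dimensionless-model settings: the functional form of the MAP
#' forcing, the baseline of the coupling weight, which drivers act, the ODE
#' solver settings and the transitioned-state threshold.
#'
#' @param map_form `"monotone_ramp"` (default): the MAP forcing ramps
#'   linearly from 0 at the adapted mean to the critical forcing at the
#'   threshold, staying monotone on both sides; `"literal_reciprocal"`
#'   evaluates the reciprocal form verbatim for comparison runs (it diverges
#'   at the adapted mean).
#' @param coupling_baseline `"zero_baseline"` (default): a source cell in the
#'   forest state contributes nothing and a transitioned source contributes
#'   its full coupling (weight `(x+1)/2`), so forcing is referenced to the
#'   realized climate which already includes delivered moisture;
#'   `"literal_half_x"` uses weight `x/2`, which makes an all-forest network
#'   contribute a stabilizing baseline.
#' @param driver_mode `"both"` (default), `"map_only"` or `"mcwd_only"`.
#' @param dt RK4 time step, model-time units.
#' @param t_max Maximum integration time.
#' @param tol Steady-state criterion: integration stops when
#'   `max|dx/dt| < tol`.
#' @param transition_threshold State value above which a cell counts as
#'   transitioned (default 0; the stable states sit near -1 and +1).
#' @param sigma_bounds,sigma_mode,sigma_redraw Ensemble settings: bounds and
#'   mode for [sample_sigma()]; `sigma_redraw` `"per_decade"` (default,
#'   redraw for each snapshot) or `"per_member"` (one draw per member held
#'   across snapshots).
#' @param n_members Ensemble size (default 10).
#' @param guard,guard_map,guard_mcwd,guard_combine Absolute-threshold guard
#'   mode (off by default); see [guard_mask()].
#' @param retention Evapotranspiration retention of cleared land, see
#'   [apply_landuse()].
#' @param window Averaging window in hydrological years (default 10).
#' @param start_month First month of the hydrological year.
#' @param carry_deficit Carry CWD across hydrological years (default FALSE).
#' @return A list of class `model_config`.
#' @export
model_config <- function(map_form = c("monotone_ramp", "literal_reciprocal"),
                         coupling_baseline = c("zero_baseline", "literal_half_x"),
                         driver_mode = c("both", "map_only", "mcwd_only"),
                         dt = 0.01, t_max = 500, tol = 1e-8,
                         transition_threshold = 0,
                         sigma_bounds = c(0.75, 1.25),
                         sigma_mode = "uniform_iid",
                         sigma_redraw = c("per_decade", "per_member"),
                         n_members = 10,
                         guard = FALSE, guard_map = 1850, guard_mcwd = 350,
                         guard_combine = "and",
                         retention = 0,
                         window = 10, start_month = 10,
                         carry_deficit = FALSE) {
  if (dt <= 0 || t_max <= 0) stop_input("`dt` and `t_max` must be positive.")
  structure(list(
    c_star = c_star(),
    map_form = match.arg(map_form),
    coupling_baseline = match.arg(coupling_baseline),
    driver_mode = match.arg(driver_mode),
    dt = dt, t_max = t_max, tol = tol,
    transition_threshold = transition_threshold,
    sigma_bounds = sigma_bounds,
    sigma_mode = sigma_mode,
    sigma_redraw = match.arg(sigma_redraw),
    n_members = n_members,
    guard = guard, guard_map = guard_map, guard_mcwd = guard_mcwd,
    guard_combine = guard_combine,
    retention = retention,
    window = window, start_month = start_month,
    carry_deficit = carry_deficit
  ), class = "model_config")
}

#' MAP forcing component
#'
#' Converts a cell's windowed MAP into a dimensionless forcing on the fold
#' normal form. The default monotone ramp is 0 at the adapted mean `mu`,
#' reaches the critical forcing `sqrt(4/27)` exactly at `map_crit`, and is
#' negative (stabilizing) for wetter-than-mean conditions. The literal
#' reciprocal form shares those two anchor points but diverges at
#' `map_value = mu`; it is retained for comparison runs.
#'
#' @param map_value Windowed MAP, mm/yr (vectorized).
#' @param mu Adapted mean MAP, mm/yr.
#' @param map_crit Critical MAP, mm/yr (must be < `mu`).
#' @param form `"monotone_ramp"` or `"literal_reciprocal"`.
#' @return Dimensionless forcing.
#' @export
#' @examples
#' c_map(1850, mu = 2000, map_crit = 1700) # half-way up the ramp
c_map <- function(map_value, mu, map_crit, form = c("monotone_ramp", "literal_reciprocal")) {
  form <- match.arg(form)
  if (any(mu <= map_crit)) stop_input("degenerate threshold: need `mu > map_crit`.")
  if (form == "monotone_ramp") {
    c_star() * (mu - map_value) / (mu - map_crit)
  } else {
    c_star() * (map_crit - mu) / (map_value - mu)
  }
}

#' MCWD forcing component
#'
#' Linear in the windowed MCWD: 0 at the adapted mean, the critical forcing
#' `sqrt(4/27)` at `mcwd_crit`, negative (stabilizing) for wetter-than-mean
#' dry seasons.
#'
#' @param mcwd_value Windowed MCWD, mm/yr (vectorized).
#' @param mu Adapted mean MCWD, mm/yr.
#' @param mcwd_crit Critical MCWD, mm/yr (must be > `mu`).
#' @return Dimensionless forcing.
#' @export
c_mcwd <- function(mcwd_value, mu, mcwd_crit) {
  if (any(mcwd_crit <= mu)) stop_input("degenerate threshold: need `mcwd_crit > mu`.")
  c_star() * (mcwd_value - mu) / (mcwd_crit - mu)
}

#' Combine two forcing components
#'
#' Combines the MAP and MCWD forcings as
#' `max + (1 - max/c*) * min`, which is algebraically
#' `a + b - a*b/c*`: symmetric, monotone in each component while both are
#' below the critical forcing `c* = sqrt(4/27)`, and capped so the combined
#' value reaches `c*` exactly when either component does. Once the larger
#' component is at or beyond `c*`, the cell is past its tipping point and
#' the combined forcing equals that component (the weaker one no longer
#' discounts it), which keeps the combination continuous and monotone for
#' arbitrarily strong forcing.
#'
#' @param c_a,c_b Dimensionless forcing components (may be negative,
#'   i.e. stabilizing).
#' @return Combined dimensionless forcing.
#' @export
#' @examples
#' combine_components(0.2, 0.1)
combine_components <- function(c_a, c_b) {
  cs <- c_star()
  hi <- pmax(c_a, c_b)
  lo <- pmin(c_a, c_b)
  ifelse(hi >= cs, hi, hi + (1 - hi / cs) * lo)
}

#' Per-cell forcing components from windowed hydrology
#'
#' Evaluates the MAP and MCWD forcing components and their combination for
#' every tippable cell, honouring `driver_mode` ablations (a single-driver
#' mode uses only that component as the total forcing).
#'
#' @param hydro Tibble with `cell_id`, windowed `map` and `mcwd` (mm/yr).
#' @param profile Threshold profile from [compute_thresholds()].
#' @param config A [model_config()].
#' @return A tibble (`cell_id`, `c_map`, `c_mcwd`, `c_crit`, `tippable`).
#' @export
forcing_components <- function(hydro, profile, config = model_config()) {
  df <- dplyr::inner_join(hydro, profile, by = "cell_id")
  tip <- df$tippable
  cm <- rep(0, nrow(df)); cw <- rep(0, nrow(df))
  cm[tip] <- c_map(df$map[tip], df$mu_map[tip], df$map_crit[tip], form = config$map_form)
  cw[tip] <- c_mcwd(df$mcwd[tip], df$mu_mcwd[tip], df$mcwd_crit[tip])
  cc <- switch(config$driver_mode,
    both = combine_components(cm, cw),
    map_only = cm,
    mcwd_only = cw
  )
  cc[!tip] <- 0 # non-tippable cells are clamped to forest in the dynamics
  tibble::tibble(cell_id = df$cell_id, c_map = cm, c_mcwd = cw,
                 c_crit = cc, tippable = tip)
}
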