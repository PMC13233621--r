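# Shared mean/sd machinery for adaptation stats on an existing hydro series.
adaptation_stats <- function(hs, window, sd_type = "population") {
  hs <- dplyr::filter(hs, .data$hydro_year %in% !!window)
  sdev <- if (sd_type == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else stats::sd
  hs |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      mu_map = mean(.data$map), delta_map = sdev(.data$map),
      mu_mcwd = mean(.data$mcwd), delta_mcwd = sdev(.data$mcwd),
      n_years = dplyr::n(), .groups = "drop"
    )
}

#' Monte Carlo ensemble over adaptation uncertainty
#'
#' Runs every snapshot for every ensemble member, redrawing the adaptive
#' capacity multiplier `sigma` per member (and, by default, per snapshot)
#' from a uniform distribution, and aggregates per-cell transition risk (the
#' fraction of members in which a cell ends transitioned), area-weighted
#' transitioned-area trajectories with their across-member standard
#' deviation, and pooled cause attribution. Fully reproducible from
#' `master_seed`.
#'
#' @param snapshots A named list; each element a list with `hydro` (tibble
#'   `cell_id`, `map`, `mcwd` of windowed values), `effects`
#'   ([link_effects()]) and optionally `landuse` (tibble `cell_id`,
#'   `fraction`).
#' @param profile_base Adaptation statistics from [fit_adaptation()].
#' @param grid Grid tibble.
#' @param config A [model_config()]; `n_members`, `sigma_bounds`,
#'   `sigma_mode` and `sigma_redraw` come from here.
#' @param master_seed Integer master seed for all randomness.
#' @return A list of class `tipping_ensemble` with elements `risk` (per
#'   cell and snapshot), `area` (per snapshot: `area_mean_pct`,
#'   `area_sd_pct`, `deforested_pct`, `area_forest_mean_pct`,
#'   `area_forest_sd_pct`), `plane` (basin-mean windowed MAP/MCWD per
#'   snapshot with transitioned area and high-risk flag), `attribution`
#'   (pooled counts and shares), `states` (per member, snapshot and cell)
#'   and `config`.
#' @export
run_ensemble <- function(snapshots, profile_base, grid, config = model_config(),
                         master_seed = 1L) {
  n_members <- config$n_members
  if (n_members < 1) stop_input("`n_members` must be >= 1.")
  labels <- names(snapshots)
  if (is.null(labels)) labels <- as.character(seq_along(snapshots))
  n_snap <- length(snapshots)
  seeds <- matrix(derive_seeds(master_seed, n_members * n_snap),
                  nrow = n_members, ncol = n_snap)

  area_w <- setNames(grid$area, as.character(grid$cell_id))
  total_area <- sum(grid$area)

  states <- vector("list", n_members * n_snap)
  area_rows <- vector("list", n_members * n_snap)
  k <- 0
  for (m in seq_len(n_members)) {
    for (s in seq_len(n_snap)) {
      seed <- if (config$sigma_redraw == "per_decade") seeds[m, s] else seeds[m, 1]
      sigma <- sample_sigma(grid, bounds = config$sigma_bounds,
                            mode = config$sigma_mode,
                            map_reference = dplyr::rename(
                              dplyr::select(profile_base, "cell_id", "mu_map"),
                              map = "mu_map"),
                            seed = seed)
      profile <- suppressWarnings(compute_thresholds(profile_base, sigma))
      snap <- run_snapshot(snapshots[[s]]$hydro, snapshots[[s]]$effects,
                           profile, landuse = snapshots[[s]]$landuse,
                           config = config)
      aw <- area_w[as.character(snap$cell_id)]
      defor_area <- sum(aw * snap$deforested_fraction)
      trans_area <- sum(aw * snap$transitioned)
      forest_den <- total_area - defor_area
      k <- k + 1
      states[[k]] <- tibble::tibble(
        member = m, snapshot = labels[s], cell_id = snap$cell_id,
        transitioned = snap$transitioned, reason = snap$reason,
        forced = snap$forced
      )
      area_rows[[k]] <- tibble::tibble(
        member = m, snapshot = labels[s],
        area_pct = 100 * trans_area / total_area,
        area_forest_pct = if (forest_den > 0) {
          100 * sum(aw * (snap$transitioned & !snap$forced)) / forest_den
        } else 0,
        deforested_pct = 100 * defor_area / total_area
      )
    }
  }
  states <- dplyr::bind_rows(states)
  per_member <- dplyr::bind_rows(area_rows)

  risk <- states |>
    dplyr::group_by(.data$snapshot, .data$cell_id) |>
    dplyr::summarise(risk = mean(.data$transitioned), .groups = "drop")

  area <- per_member |>
    dplyr::group_by(.data$snapshot) |>
    dplyr::summarise(
      area_mean_pct = mean(.data$area_pct),
      area_sd_pct = stats::sd(.data$area_pct),
      area_forest_mean_pct = mean(.data$area_forest_pct),
      area_forest_sd_pct = stats::sd(.data$area_forest_pct),
      deforested_pct = mean(.data$deforested_pct),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("_sd_pct"),
                                ~ ifelse(is.na(.x), 0, .x))) |>
    dplyr::arrange(match(.data$snapshot, labels))

  plane <- purrr::map2_dfr(snapshots, labels, function(sn, lb) {
    h <- sn$hydro
    aw <- area_w[as.character(h$cell_id)]
    tibble::tibble(snapshot = lb,
                   map = sum(aw * h$map) / sum(aw),
                   mcwd = sum(aw * h$mcwd) / sum(aw))
  }) |>
    dplyr::left_join(dplyr::select(area, "snapshot", area_pct = "area_mean_pct"),
                     by = "snapshot") |>
    risk_plane()

  attribution <- attribution_shares(states)

  structure(list(risk = risk, area = area, plane = plane,
                 attribution = attribution, states = states,
                 per_member = per_member,
                 config = config, master_seed = master_seed),
            class = "tipping_ensemble")
}

#' Run a full synthetic scenario end to end
#'
#' The pipeline driver: generates the grid and the monthly climate, fits the
#' adaptation statistics on the historical window, and for each snapshot
#' decade builds the moisture-recycling network on that decade's
#' climatology, derives its link effects, reads off the deforestation
#' fractions, and runs the Monte Carlo ensemble of committed-transition
#' snapshots.
#'
#' @param preset A [scenario_preset()] (possibly modified, e.g. localized
#'   `trend_weight` in its `climate`).
#' @param nx,ny,cell_area Grid dimensions and per-cell area (km^2).
#' @param config A [model_config()].
#' @param master_seed Integer master seed for the ensemble draws.
#' @param snapshot_starts First hydrological years of the snapshot windows
#'   (default the eight decades 2020, 2030, ..., 2090).
#' @param drying_scale Multiplier on both climate trends (scenario-severity
#'   scaling experiments).
#' @param ablate_network If `TRUE`, all moisture links are removed (cascade
#'   ablation): transitions can then only be caused directly.
#' @return A `tipping_ensemble` (see [run_ensemble()]) with the adaptation
#'   profile and grid attached as attributes.
#' @export
run_scenario <- function(preset, nx = 20, ny = 20, cell_area = 10000,
                         config = model_config(), master_seed = 1L,
                         snapshot_starts = seq(2020, 2090, by = 10),
                         drying_scale = 1, ablate_network = FALSE) {
  grid <- make_grid(nx, ny, cell_area)
  cp <- preset$climate
  cp$trend_map_per_decade <- cp$trend_map_per_decade * drying_scale
  cp$trend_dry_intensity_per_decade <- cp$trend_dry_intensity_per_decade * drying_scale

  all_years <- min(preset$adaptation_years):max(preset$scenario_years)
  clim <- simulate_climate(grid, cp, all_years)
  hs <- hydro_series(clim$precip, clim$evap, start_month = config$start_month,
                     carry_deficit = config$carry_deficit)
  adapt_window <- preset$adaptation_years[
    preset$adaptation_years %in% unique(hs$hydro_year) &
      preset$adaptation_years < min(preset$scenario_years)]
  profile_base <- adaptation_stats(hs, adapt_window)

  landuse <- if (!is.null(preset$deforestation)) {
    do.call(make_deforestation, c(list(grid = grid), preset$deforestation))
  } else NULL

  window <- config$window
  snapshots <- lapply(snapshot_starts, function(d) {
    yrs <- d:(d + window - 1)
    hydro_w <- hs |>
      dplyr::filter(.data$hydro_year %in% yrs) |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(map = mean(.data$map), mcwd = mean(.data$mcwd),
                       .groups = "drop")
    effects <- if (ablate_network) {
      structure(tibble::tibble(source = integer(), target = integer(),
                               delta_map = numeric(), delta_mcwd = numeric()),
                class = c("link_effects", "tbl_df", "tbl", "data.frame"))
    } else {
      net <- build_network(grid, preset$network, clim$precip, clim$evap,
                           years = yrs)
      link_effects(net, start_month = config$start_month)
    }
    list(hydro = hydro_w, effects = effects,
         landuse = if (is.null(landuse)) NULL else {
           landuse_at(landuse, max(yrs), grid)
         })
  })
  names(snapshots) <- paste0(snapshot_starts, "s")

  res <- run_ensemble(snapshots, profile_base, grid, config = config,
                      master_seed = master_seed)
  attr(res, "profile_base") <- profile_base
  attr(res, "grid") <- grid
  attr(res, "preset_name") <- preset$name
  res
}
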