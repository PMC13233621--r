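#' Read and write monthly fields as long-format CSV
#'
#' Fields travel on disk as long-format CSV (`cell_id`, `year`, `month`,
#' `value`). Reading validates the time axis: every cell must have a
#' contiguous, gap-free monthly series (a missing month is a parse error
#' naming the offending cell, never a silent fill).
#'
#' @param path File path.
#' @param field Long monthly field tibble.
#' @return `read_field()` returns the field tibble; `write_field()` returns
#'   `path` invisibly.
#' @export
read_field <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_integer(), year = readr::col_integer(),
    month = readr::col_integer(), value = readr::col_double()))
  if (!all(c("cell_id", "year", "month", "value") %in% names(df))) {
    stop_input("field file must have columns cell_id, year, month, value.")
  }
  if (any(!df$month %in% 1:12)) stop_input("months must be in 1..12.")
  bad <- df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(ok = {
      key <- sort(.data$year * 12L + .data$month)
      length(key) > 0 && !anyDuplicated(key) && all(diff(key) == 1L)
    }, .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop_input("cell %s has a missing or duplicated month in its series.",
               bad$cell_id[1])
  }
  dplyr::arrange(df, .data$cell_id, .data$year, .data$month)
}

#' @rdname read_field
#' @export
write_field <- function(field, path) {
  readr::write_csv(dplyr::select(field, "cell_id", "year", "month", "value"), path)
  invisible(path)
}

#' Read and write moisture networks as edge-list CSV
#'
#' Networks travel as edge lists (`source`, `target`, `month`, `flow` in
#' mm/month). Zero-weight links are dropped on write. Reading rejects
#' duplicate (source, target, month) rows and negative weights. Supplying
#' monthly precipitation/evaporation fields on read re-attaches the
#' climatology needed by [link_effects()].
#'
#' @param path File path.
#' @param network A `moisture_network` tibble.
#' @param precip,evap Optional monthly fields to re-attach a climatology.
#' @param years Optional years for the climatology.
#' @return `read_network()` returns a `moisture_network`; `write_network()`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, precip = NULL, evap = NULL, years = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    source = readr::col_integer(), target = readr::col_integer(),
    month = readr::col_integer(), flow = readr::col_double()))
  if (any(df$flow < 0)) stop_input("negative link weight in network file.")
  if (any(!df$month %in% 1:12)) stop_input("link months must be in 1..12.")
  if (anyDuplicated(df[c("source", "target", "month")]) > 0) {
    stop_input("duplicate (source, target, month) link rows in network file.")
  }
  p_clim <- if (!is.null(precip)) monthly_climatology(precip, years) else NULL
  e_clim <- if (!is.null(evap)) monthly_climatology(evap, years) else NULL
  new_moisture_network(dplyr::arrange(df, .data$source, .data$target, .data$month),
                       p_clim, e_clim)
}

#' @rdname read_network
#' @export
write_network <- function(network, path) {
  out <- tibble::as_tibble(network) |>
    dplyr::filter(.data$flow > 0) |>
    dplyr::select("source", "target", "month", "flow")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write land-use series as CSV
#'
#' @param path File path.
#' @param landuse A `landuse_series` tibble (`cell_id`, `year`, `fraction`).
#' @return `read_landuse()` returns the series; `write_landuse()` returns
#'   `path` invisibly.
#' @export
read_landuse <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_integer(), year = readr::col_integer(),
    fraction = readr::col_double()))
  check_fraction(df$fraction, "fraction")
  dec <- df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(.data$fraction) >= -1e-12), .groups = "drop")
  if (any(!dec$ok)) stop_input("deforested fractions must be non-decreasing in time.")
  structure(dplyr::arrange(df, .data$cell_id, .data$year),
            class = c("landuse_series", "tbl_df", "tbl", "data.frame"))
}

#' @rdname read_landuse
#' @export
write_landuse <- function(landuse, path) {
  readr::write_csv(dplyr::select(landuse, "cell_id", "year", "fraction"), path)
  invisible(path)
}

#' Read and write adaptation/threshold profiles as CSV
#'
#' @param path File path.
#' @param profile A profile tibble from [compute_thresholds()].
#' @return `read_profile()` returns the profile; `write_profile()` returns
#'   `path` invisibly.
#' @export
read_profile <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(profile, path)
  invisible(path)
}

#' Build and write a run manifest
#'
#' Captures everything needed to reproduce a run byte-identically: the model
#' configuration and mode flags, the master seed, the package version and
#' optional input-file hashes.
#'
#' @param config A [model_config()].
#' @param master_seed Integer master seed of the run.
#' @param inputs Optional named character vector of input file paths; their
#'   md5 hashes are recorded.
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest as a list (invisibly when written).
#' @export
run_manifest <- function(config, master_seed, inputs = NULL, path = NULL) {
  manifest <- list(
    package = "raincascade",
    version = as.character(utils::packageVersion("raincascade")),
    master_seed = as.integer(master_seed),
    config = unclass(config),
    input_hashes = if (!is.null(inputs)) {
      as.list(setNames(tools::md5sum(inputs), names(inputs)))
    } else NULL
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
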