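# Internal helpers: validation, field <-> matrix conversion, seed streams.

stop_input <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "raincascade_input_error")

check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_input("`%s` must lie in [0, 1].", name)
  }
  invisible(x)
}

# Monthly fields travel as long tibbles (cell_id, year, month, value); the
# numerics want a cells x months matrix with a (year, month) column index.
field_to_matrix <- function(field) {
  stopifnot(all(c("cell_id", "year", "month", "value") %in% names(field)))
  cells <- sort(unique(field$cell_id))
  times <- dplyr::distinct(field, .data$year, .data$month) |>
    dplyr::arrange(.data$year, .data$month)
  key <- times$year * 12L + (times$month - 1L)
  if (any(diff(key) != 1L)) stop_input("monthly field is not contiguous in time.")
  col <- match(field$year * 12L + (field$month - 1L), key)
  row <- match(field$cell_id, cells)
  m <- matrix(NA_real_, nrow = length(cells), ncol = length(key),
              dimnames = list(cells, NULL))
  m[cbind(row, col)] <- field$value
  if (anyNA(m)) stop_input("monthly field has missing cell/month combinations.")
  attr(m, "years") <- times$year
  attr(m, "months") <- times$month
  m
}

matrix_to_field <- function(m) {
  cells <- as.integer(rownames(m))
  tibble::tibble(
    cell_id = rep(cells, times = ncol(m)),
    year = rep(attr(m, "years"), each = nrow(m)),
    month = rep(attr(m, "months"), each = nrow(m)),
    value = as.vector(m)
  ) |>
    dplyr::arrange(.data$cell_id, .data$year, .data$month)
}

# Independent seed streams derived from one master seed; keeps every derived
# seed a valid 32-bit integer.
derive_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
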