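#' Build a rectangular basin grid
#'
#' Creates the cell registry used by every downstream stage: an abstract
#' rectangular grid with row-major, zero-based cell ids, per-cell areas and a
#' basin mask. The model never uses geometry beyond inter-cell distances and
#' areas, so no map projection is applied; `x` increases eastward and `y`
#' northward in grid units.
#'
#' @param nx,ny Number of columns and rows (both >= 1).
#' @param cell_area Area of each cell in km^2.
#' @return A tibble with columns `cell_id` (integer, `0..nx*ny-1`), `x`, `y`
#'   (grid coordinates), `area` (km^2) and `basin` (logical; all `TRUE` by
#'   default).
#' @export
#' @examples
#' make_grid(4, 3, 10000)
make_grid <- function(nx, ny, cell_area = 10000) {
  if (length(nx) != 1 || length(ny) != 1 || nx < 1 || ny < 1 ||
      nx != round(nx) || ny != round(ny)) {
    stop_input("`nx` and `ny` must be positive integers.")
  }
  if (cell_area <= 0) stop_input("`cell_area` must be positive.")
  nx <- as.integer(nx); ny <- as.integer(ny)
  tibble::tibble(
    cell_id = seq_len(nx * ny) - 1L,
    x = rep(seq_len(nx), times = ny) - 1L,
    y = rep(seq_len(ny), each = nx) - 1L,
    area = cell_area,
    basin = TRUE
  )
}

n_basin_cells <- function(grid) sum(grid$basin)
basin_area <- function(grid) sum(grid$area[grid$basin])
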