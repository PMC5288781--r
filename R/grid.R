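#' Define a regular longitude-latitude grid
#'
#' A grid specification underlies both the current-field grid and the (usually
#' finer) coastal cell grid. Cells are square in degrees; coordinates refer to
#' cell centers.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain bounds in decimal degrees.
#' @param resolution Cell size in degrees (one value for both axes).
#' @return A `grid_spec` object: a list with the bounds, `resolution`, and the
#'   cell counts `n_lon`, `n_lat`.
#' @examples
#' grid_spec(-26, -22, 14, 18, resolution = 0.05)
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0) {
    abort("`resolution` must be a single positive number (degrees per cell)")
  }
  if (lon_max <= lon_min || lat_max <= lat_min) {
    abort("grid bounds must satisfy lon_max > lon_min and lat_max > lat_min")
  }
  n_lon <- as.integer(round((lon_max - lon_min) / resolution))
  n_lat <- as.integer(round((lat_max - lat_min) / resolution))
  if (n_lon < 1 || n_lat < 1) abort("grid must contain at least one cell per axis")
  structure(
    list(
      lon_min = lon_min, lon_max = lon_max,
      lat_min = lat_min, lat_max = lat_max,
      resolution = resolution, n_lon = n_lon, n_lat = n_lat
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g deg, lon [%g, %g], lat [%g, %g]\n",
    x$n_lon, x$n_lat, x$resolution, x$lon_min, x$lon_max, x$lat_min, x$lat_max
  ))
  invisible(x)
}

# cell-center coordinate vectors
grid_lons <- function(grid) grid$lon_min + (seq_len(grid$n_lon) - 0.5) * grid$resolution
grid_lats <- function(grid) grid$lat_min + (seq_len(grid$n_lat) - 0.5) * grid$resolution

# map positions to (row = lat index, col = lon index); NA outside the domain
grid_locate <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$resolution) + 1
  row <- floor((lat - grid$lat_min) / grid$resolution) + 1
  bad <- col < 1 | col > grid$n_lon | row < 1 | row > grid$n_lat
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# linear cell id for a (row, col) pair on a grid stored [lat, lon]
grid_cell_id <- function(grid, row, col) {
  as.integer(row + (col - 1L) * grid$n_lat)
}
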