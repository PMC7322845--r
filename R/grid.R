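#' Regular longitude/latitude grid specification
#'
#' Cells are half-open intervals [west, east) x [south, north). The origin is
#' snapped outward to multiples of the cell size in global coordinates so that
#' grids built from different data sets with the same cell size share cell
#' boundaries.
#'
#' @param cell_deg Cell size in decimal degrees (> 0).
#' @param lon_range,lat_range Length-2 numeric vectors giving the extent to
#'   cover; the grid is expanded to whole cells.
#' @return An object of class `grid_spec` with elements `cell_deg`, `origin`
#'   (lon/lat of the lower-left corner), `n_lon`, `n_lat`, and cell-centre
#'   coordinate vectors `lon_centers`, `lat_centers`.
#' @examples
#' g <- grid_spec(0.5, c(20, 40), c(-55, -40))
#' g$n_lon
#' @export
grid_spec <- function(cell_deg, lon_range, lat_range) {
  stopifnot(is.numeric(cell_deg), length(cell_deg) == 1, cell_deg > 0)
  lon_range <- range(lon_range)
  lat_range <- range(lat_range)
  if (diff(lon_range) == 0 || diff(lat_range) == 0)
    stop("grid_spec: degenerate extent", call. = FALSE)
  o_lon <- floor(lon_range[1] / cell_deg) * cell_deg
  o_lat <- floor(lat_range[1] / cell_deg) * cell_deg
  n_lon <- ceiling((lon_range[2] - o_lon) / cell_deg - 1e-9)
  n_lat <- ceiling((lat_range[2] - o_lat) / cell_deg - 1e-9)
  structure(list(
    cell_deg = cell_deg,
    origin = c(lon = o_lon, lat = o_lat),
    n_lon = n_lon, n_lat = n_lat,
    lon_centers = o_lon + (seq_len(n_lon) - 0.5) * cell_deg,
    lat_centers = o_lat + (seq_len(n_lat) - 0.5) * cell_deg
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.3f deg, origin (%.3f, %.3f)\n",
              x$n_lon, x$n_lat, x$cell_deg, x$origin[1], x$origin[2]))
  invisible(x)
}

# Half-open cell index (1-based) of points; NA outside the grid.
grid_cell_index <- function(grid, lon, lat) {
  i <- floor((lon - grid$origin["lon"]) / grid$cell_deg) + 1
  j <- floor((lat - grid$origin["lat"]) / grid$cell_deg) + 1
  i[i < 1 | i > grid$n_lon] <- NA
  j[j < 1 | j > grid$n_lat] <- NA
  data.frame(ilon = as.integer(i), ilat = as.integer(j))
}
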