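#' Gridded field time series
#'
#' A light container for lat-lon-time model output: a 3-d array of values
#' with coordinate vectors, a static land mask, and units. Longitudes are
#' stored in [-180, 180].
#'
#' @param values Numeric array `[lat, lon, time]`.
#' @param lats,lons Coordinate vectors (degrees), matching the array dims.
#' @param times Time coordinate (model years), matching the third dim.
#' @param mask Logical `[lat, lon]` matrix, `TRUE` = land. Default all land.
#' @param units,name Units string and variable name (metadata).
#' @return A `grid_field` object.
#' @export
grid_field <- function(values, lats, lons, times, mask = NULL,
                       units = "", name = "") {
  if (length(dim(values)) != 3L) abort("`values` must be a [lat, lon, time] array.")
  d <- dim(values)
  if (d[1] != length(lats) || d[2] != length(lons) || d[3] != length(times)) {
    abort("Array dims must match `lats`, `lons`, `times`.")
  }
  if (any(lons > 180)) lons <- ((lons + 180) %% 360) - 180
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2])) abort("`mask` must be a [lat, lon] matrix.")
  structure(
    list(values = values, lats = as.numeric(lats), lons = as.numeric(lons),
         times = as.numeric(times), mask = mask, units = units, name = name),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("grid_field `%s` [%s]: %d lat x %d lon x %d time, %d/%d land cells\n",
              x$name, x$units, length(x$lats), length(x$lons), length(x$times),
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
as_tibble.grid_field <- function(x, ...) {
  grid <- tidyr::expand_grid(time = x$times, lon = x$lons, lat = x$lats)
  grid$value <- as.vector(x$values)
  grid$land <- rep(as.vector(x$mask), times = length(x$times))
  grid[, c("lat", "lon", "time", "value", "land")]
}

# flatten to time x space with cells in a fixed (lat, lon) order
field_space_matrix <- function(field, land_only = FALSE) {
  d <- dim(field$values)
  X <- matrix(aperm(field$values, c(3, 1, 2)), nrow = d[3])
  cells <- tidyr::expand_grid(lon = field$lons, lat = field$lats)[, c("lat", "lon")]
  cells$land <- as.vector(field$mask)
  keep <- if (land_only) which(cells$land) else seq_len(nrow(cells))
  list(X = X[, keep, drop = FALSE], cells = cells[keep, ])
}
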