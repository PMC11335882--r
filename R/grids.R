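#' Regular latitude-longitude grid
#'
#' Defines a regular lat/lon mesh with analytically computed spherical cell
#' areas. Cells are indexed row-major with longitude varying fastest, so cell
#' \code{k} corresponds to \code{(lat[(k - 1) %/% nlon + 1], lon[(k - 1) %% nlon + 1])}.
#'
#' Cell areas use the exact spherical formula
#' \eqn{A = R^2 \Delta\lambda (\sin\varphi_+ - \sin\varphi_-)} with
#' \eqn{\varphi_\pm} the cell's bounding latitudes (half a grid step either
#' side of the centre) and \eqn{R} the mean Earth radius.
#'
#' @param lon vector of cell-centre longitudes (degrees, regular spacing)
#' @param lat vector of cell-centre latitudes (degrees, regular spacing)
#' @param earth_radius_km Earth radius used for cell areas (km)
#' @return an object of class \code{ws_grid} with fields \code{lon},
#'   \code{lat}, \code{nlon}, \code{nlat}, \code{ncell},
#'   \code{cell_lon}, \code{cell_lat} (per-cell coordinates) and
#'   \code{cell_area_km2}
#' @export
ws_grid <- function(lon, lat, earth_radius_km = 6371.0088) {
  stopifnot(length(lon) >= 1, length(lat) >= 1)
  if (length(lon) > 2 && stats::sd(diff(lon)) > 1e-8)
    stop("lon must be regularly spaced")
  if (length(lat) > 2 && stats::sd(diff(lat)) > 1e-8)
    stop("lat must be regularly spaced")
  dlon <- if (length(lon) > 1) abs(diff(lon)[1]) else 1
  dlat <- if (length(lat) > 1) abs(diff(lat)[1]) else 1
  cell_lon <- rep(lon, times = length(lat))
  cell_lat <- rep(lat, each = length(lon))
  phi_hi <- (cell_lat + dlat / 2) * pi / 180
  phi_lo <- (cell_lat - dlat / 2) * pi / 180
  area <- earth_radius_km^2 * (dlon * pi / 180) * (sin(phi_hi) - sin(phi_lo))
  structure(list(
    lon = lon, lat = lat, nlon = length(lon), nlat = length(lat),
    ncell = length(lon) * length(lat),
    cell_lon = cell_lon, cell_lat = cell_lat,
    cell_area_km2 = abs(area), dlon = dlon, dlat = dlat
  ), class = "ws_grid")
}

#' @export
print.ws_grid <- function(x, ...) {
  cat(sprintf("<ws_grid> %d x %d cells (%.3g-%.3g E, %.3g-%.3g N)\n",
              x$nlon, x$nlat, min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

#' Daily gridded surface weather
#'
#' Container for daily weather on a \code{\link{ws_grid}}. All fields are
#' cell-by-day matrices (\code{ncell} rows, one column per date).
#'
#' @param grid a \code{ws_grid}
#' @param dates vector of consecutive \code{Date}s
#' @param temp_c noon 2-m air temperature (deg C)
#' @param rh_pct relative humidity (0-100)
#' @param wind_kmh 10-m wind speed (km/h, >= 0)
#' @param precip_mm 24-h accumulated precipitation (mm, >= 0)
#' @param tmax_c daily maximum temperature; defaults to \code{temp_c}
#' @return an object of class \code{weather_grid}
#' @export
weather_grid <- function(grid, dates, temp_c, rh_pct, wind_kmh, precip_mm,
                         tmax_c = NULL) {
  stopifnot(inherits(grid, "ws_grid"), inherits(dates, "Date"))
  nd <- length(dates)
  if (nd > 1 && any(diff(dates) != 1)) stop("dates must be consecutive days")
  req <- list(temp_c = temp_c, rh_pct = rh_pct, wind_kmh = wind_kmh,
              precip_mm = precip_mm)
  for (nm in names(req)) {
    v <- req[[nm]]
    if (is.null(v)) stop("missing required weather variable: ", nm)
    if (!is.matrix(v) || nrow(v) != grid$ncell || ncol(v) != nd)
      stop(sprintf("%s must be a %d x %d matrix", nm, grid$ncell, nd))
  }
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE))
    stop("rh_pct out of range [0, 100]")
  if (any(wind_kmh < 0, na.rm = TRUE)) stop("wind_kmh must be >= 0")
  if (any(precip_mm < 0, na.rm = TRUE)) stop("precip_mm must be >= 0")
  if (is.null(tmax_c)) tmax_c <- temp_c
  structure(list(grid = grid, dates = dates, temp_c = temp_c, rh_pct = rh_pct,
                 wind_kmh = wind_kmh, precip_mm = precip_mm, tmax_c = tmax_c),
            class = "weather_grid")
}

#' @export
print.weather_grid <- function(x, ...) {
  cat(sprintf("<weather_grid> %d cells x %d days (%s .. %s)\n",
              x$grid$ncell, length(x$dates), min(x$dates), max(x$dates)))
  invisible(x)
}

#' Write / read a cell-by-day grid field as long-format CSV
#'
#' Plain-text serialization for gridded daily fields: one row per (cell, day)
#' with the cell's coordinates, suitable for interchange and for run
#' manifests. Values are written at full double precision.
#'
#' @param x cell-by-day matrix
#' @param grid the \code{ws_grid} the rows refer to
#' @param dates column dates
#' @param file output path
#' @param name value column name
#' @export
write_grid_csv <- function(x, grid, dates, file, name = "value") {
  df <- data.frame(
    cell = rep(seq_len(grid$ncell), times = length(dates)),
    lon = rep(grid$cell_lon, times = length(dates)),
    lat = rep(grid$cell_lat, times = length(dates)),
    date = rep(as.character(dates), each = grid$ncell),
    value = as.vector(x)
  )
  names(df)[5] <- name
  utils::write.csv(format(df, digits = 17, trim = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_grid_csv
#' @param file CSV written by \code{write_grid_csv}
#' @return list with \code{values} (cell-by-day matrix), \code{dates}
#' @export
read_grid_csv <- function(file) {
  df <- utils::read.csv(file)
  dates <- as.Date(unique(df$date))
  ncell <- max(df$cell)
  list(values = matrix(df[[5]], nrow = ncell), dates = dates)
}
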