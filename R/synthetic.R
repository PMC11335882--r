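# Synthetic-data generators with known ground truth. These emulate the
# pipeline's real-data inputs -- reanalysis-style daily surface weather and
# 500-hPa heights, binary snow-cover series, root-zone soil-moisture series
# -- at desk scale, with implanted episodes recorded in a truth bundle so
# every analysis stage has a recovery test. They are deliberately simple
# statistical emulators (seasonal cycle + AR(1) noise, thinned-gamma
# precipitation), not physical models.

#' Scenario configuration for the synthetic weather generator
#'
#' Defaults define the package's reference study conditions: a 20 x 20 cell
#' 0.5-degree boreal grid, a seasonal temperature cycle from about -5 deg C
#' in winter to about +16 deg C in midsummer, AR(1) day-to-day persistence
#' 0.7 with 3 deg C anomaly SD, wet-day probability 0.35 with gamma
#' (shape 0.7, scale 6 mm) amounts, and AR(1) 500-hPa heights around a
#' seasonal mean.
#'
#' @param nlon,nlat grid size; @param lon0,lat0 south-west cell centre;
#' @param dres grid step (deg)
#' @param start_year first year; @param n_years number of calendar years
#' @param temp_mean annual-mean temperature at the grid's mid latitude
#' @param temp_seasonal_amp half-range of the seasonal cycle (deg C)
#' @param temp_ar1 AR(1) coefficient of daily temperature anomalies
#' @param temp_sd stationary SD of daily temperature anomalies (deg C)
#' @param tmax_offset mean daily-max minus noon temperature (deg C)
#' @param lat_gradient deg C per degree latitude (negative poleward)
#' @param wet_day_p wet-day probability; @param precip_shape,precip_scale
#'   gamma parameters of wet-day amounts (mm)
#' @param heights_base,heights_amp seasonal mean and half-range of 500-hPa
#'   heights (m); @param heights_ar1,heights_sd AR(1) and SD of height
#'   anomalies (m)
#' @param episodes list of implanted heat/dry episodes, each a list with
#'   \code{cells}, \code{start} (Date), \code{n_days}, \code{amp_c}
#'   (temperature boost; precipitation is zeroed for the episode)
#' @param ridges list of implanted height ridges, each a list with
#'   \code{cells}, \code{start} (Date), \code{n_days}, \code{amp_sd}
#'   (amplitude in units of the noise SD)
#' @param eval_noise_scale multiplier on height noise after
#'   \code{eval_start} (used by blocking recovery studies); default 1
#' @param eval_start Date from which \code{eval_noise_scale} applies
#' @return a \code{scenario_config} list
#' @export
scenario_config <- function(nlon = 20, nlat = 20, lon0 = -120, lat0 = 45,
                            dres = 0.5, start_year = 1991, n_years = 2,
                            temp_mean = 5.5, temp_seasonal_amp = 10.5,
                            temp_ar1 = 0.7, temp_sd = 3, tmax_offset = 5,
                            lat_gradient = -0.3, wet_day_p = 0.35,
                            precip_shape = 0.7, precip_scale = 6,
                            heights_base = 5500, heights_amp = 120,
                            heights_ar1 = 0.85, heights_sd = 40,
                            episodes = list(), ridges = list(),
                            eval_noise_scale = 1, eval_start = NULL) {
  grid <- ws_grid(lon = lon0 + dres * (seq_len(nlon) - 1),
                  lat = lat0 + dres * (seq_len(nlat) - 1))
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)), by = 1)
  structure(list(grid = grid, dates = dates,
                 temp_mean = temp_mean, temp_seasonal_amp = temp_seasonal_amp,
                 temp_ar1 = temp_ar1, temp_sd = temp_sd,
                 tmax_offset = tmax_offset, lat_gradient = lat_gradient,
                 wet_day_p = wet_day_p, precip_shape = precip_shape,
                 precip_scale = precip_scale, heights_base = heights_base,
                 heights_amp = heights_amp, heights_ar1 = heights_ar1,
                 heights_sd = heights_sd, episodes = episodes,
                 ridges = ridges, eval_noise_scale = eval_noise_scale,
                 eval_start = eval_start),
            class = "scenario_config")
}

.ar1_matrix <- function(ncell, ndays, phi, sd_stat) {
  innov <- matrix(stats::rnorm(ncell * ndays, 0, sd_stat * sqrt(1 - phi^2)),
                  ndays, ncell)
  innov[1, ] <- stats::rnorm(ncell, 0, sd_stat)
  t(apply(innov, 2, function(x) stats::filter(x, phi, method = "recursive")))
}

#' Generate synthetic gridded daily weather (and 500-hPa heights)
#'
#' Seasonal cycle plus per-cell AR(1) anomalies; precipitation as thinned
#' gamma events; relative humidity anti-correlated with temperature; heights
#' with their own seasonal cycle and AR(1) anomalies. Implanted heat/dry
#' episodes raise temperature by \code{amp_c} and zero precipitation over
#' their cells and days; implanted ridges add \code{amp_sd} noise-SDs to the
#' heights. All implants are recorded in the returned truth list.
#'
#' @param config a \code{\link{scenario_config}}
#' @param seed integer seed; the same (config, seed) pair reproduces the
#'   output bit for bit
#' @return list: \code{weather} (a \code{\link{weather_grid}}),
#'   \code{heights} (cell-by-day matrix), \code{dates}, \code{grid},
#'   \code{truth} (episodes and ridges as implanted)
#' @export
gen_weather <- function(config, seed) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  g <- config$grid
  nd <- length(config$dates)
  doy <- as.integer(format(config$dates, "%j"))
  seas <- config$temp_mean +
    config$temp_seasonal_amp * cos(2 * pi * (doy - 200) / 365.25)
  lat_term <- config$lat_gradient * (g$cell_lat - mean(g$lat))
  clim <- outer(lat_term, seas, "+")
  temp <- clim + .ar1_matrix(g$ncell, nd, config$temp_ar1, config$temp_sd)
  wet <- matrix(stats::runif(g$ncell * nd) < config$wet_day_p, g$ncell, nd)
  amount <- matrix(stats::rgamma(g$ncell * nd, shape = config$precip_shape,
                                 scale = config$precip_scale), g$ncell, nd)
  precip <- ifelse(wet, amount, 0)
  for (ep in config$episodes) {
    cols <- which(config$dates >= ep$start &
                  config$dates < ep$start + ep$n_days)
    temp[ep$cells, cols] <- temp[ep$cells, cols] + ep$amp_c
    precip[ep$cells, cols] <- 0
  }
  rh <- pmin(pmax(92 - 2 * temp + matrix(stats::rnorm(g$ncell * nd, 0, 8),
                                         g$ncell, nd), 5), 100)
  wind <- pmin(matrix(stats::rlnorm(g$ncell * nd, log(12), 0.45),
                      g$ncell, nd), 80)
  tmax <- temp + config$tmax_offset +
    matrix(stats::rnorm(g$ncell * nd, 0, 1), g$ncell, nd)

  hseas <- config$heights_base +
    config$heights_amp * cos(2 * pi * (doy - 200) / 365.25)
  hnoise <- .ar1_matrix(g$ncell, nd, config$heights_ar1, config$heights_sd)
  if (!is.null(config$eval_start)) {
    late <- config$dates >= config$eval_start
    hnoise[, late] <- hnoise[, late] * config$eval_noise_scale
  }
  heights <- matrix(rep(hseas, each = g$ncell), g$ncell, nd) + hnoise
  for (rg in config$ridges) {
    cols <- which(config$dates >= rg$start &
                  config$dates < rg$start + rg$n_days)
    heights[rg$cells, cols] <- heights[rg$cells, cols] +
      rg$amp_sd * config$heights_sd
  }
  weather <- weather_grid(g, config$dates, temp_c = temp, rh_pct = rh,
                          wind_kmh = wind, precip_mm = precip, tmax_c = tmax)
  list(weather = weather, heights = heights, dates = config$dates, grid = g,
       truth = list(episodes = config$episodes, ridges = config$ridges))
}

#' Generate synthetic snow-cover and root-zone soil-moisture series
#'
#' Snow is covered from January 1 until the implanted melt day, snow-free
#' until the re-onset day, covered again through December 31; optional
#' ephemeral late-season snow events (2 days around day 290) are shorter
#' than the main snow-free run. Root-zone soil moisture declines at a gentle
#' background rate with an implanted 14-day drying ramp per cell. The truth
#' bundle records the melt day, the analytic maximum-window drying (ramp
#' amount plus background drift over the window) and its midpoint.
#'
#' @param melt_doy per-cell melt day-of-year
#' @param ramp_amount_kg per-cell ramp drying amount (kg m-2; 0 = no ramp)
#' @param ramp_start per-cell ramp start Date
#' @param year calendar year
#' @param onset_doy snow re-onset day-of-year (default 305)
#' @param ephemeral_cells cells given a 2-day late-season snow blip
#' @param base_slope background soil-moisture decline (kg m-2 per day). The
#'   default 0.125 is exactly representable in binary so that, on no-ramp
#'   cells, every window ties exactly and the earliest-window convention is
#'   exercised deterministically.
#' @param rzsm0 soil moisture on April 1 (kg m-2)
#' @param window drying window length (days, default 14)
#' @return list: \code{snow} (cell-by-day logical, full year), \code{rzsm}
#'   (cell-by-day, April 1 - July 31), \code{rzsm_dates}, \code{truth}
#'   (melt_doy, max_drying, mid_date)
#' @export
gen_snow_rzsm <- function(melt_doy, ramp_amount_kg, ramp_start, year = 2023,
                          onset_doy = 305, ephemeral_cells = integer(),
                          base_slope = 0.125, rzsm0 = 420, window = 14) {
  nc <- length(melt_doy)
  stopifnot(length(ramp_amount_kg) == nc, length(ramp_start) == nc)
  ndays <- as.integer(as.Date(sprintf("%d-12-31", year)) -
                      as.Date(sprintf("%d-01-01", year))) + 1L
  snow <- matrix(FALSE, nc, ndays)
  for (i in seq_len(nc)) {
    if (melt_doy[i] > 1) snow[i, 1:(melt_doy[i] - 1)] <- TRUE
    snow[i, onset_doy:ndays] <- TRUE
  }
  snow[ephemeral_cells, 290:291] <- TRUE
  rzsm_dates <- seq(as.Date(sprintf("%d-04-01", year)),
                    as.Date(sprintf("%d-07-31", year)), by = 1)
  nd <- length(rzsm_dates)
  t_rel <- seq_len(nd) - 1
  rzsm <- matrix(rep(rzsm0 - base_slope * t_rel, each = nc), nc, nd)
  for (i in seq_len(nc)) {
    if (ramp_amount_kg[i] <= 0) next
    ramp_cum <- pmin(pmax(as.numeric(rzsm_dates - ramp_start[i]), 0), window) *
      ramp_amount_kg[i] / window
    rzsm[i, ] <- rzsm[i, ] - ramp_cum
  }
  search_start <- as.Date(sprintf("%d-05-01", year))
  truth_dry <- ifelse(ramp_amount_kg > 0,
                      ramp_amount_kg + base_slope * window,
                      base_slope * window)
  truth_mid <- as.Date(ifelse(ramp_amount_kg > 0,
                              ramp_start + window / 2,
                              search_start + window / 2),
                       origin = "1970-01-01")
  list(snow = snow, rzsm = rzsm, rzsm_dates = rzsm_dates,
       truth = list(melt_doy = as.integer(melt_doy), max_drying = truth_dry,
                    mid_date = truth_mid))
}

#' Synthetic blocking-recovery scenario
#'
#' Builds a multi-year height series (baseline years with full AR(1) noise,
#' evaluation year with strongly reduced noise) and implants rectangular
#' ridges of known footprint, duration and amplitude in the evaluation year.
#' Returns the heights plus a truth roster separating qualifying implants
#' (persistence >= \code{min_days} and peak area >= \code{min_area_km2})
#' from rejected ones, and the per-cell truth count of qualifying blocking
#' days.
#'
#' @param seed integer seed
#' @param n_baseline_years baseline length (default 10)
#' @param implants data.frame with \code{lon_lo}, \code{lon_hi},
#'   \code{lat_lo}, \code{lat_hi} (cell index ranges), \code{start_doy},
#'   \code{n_days}, \code{amp_sd}; NULL for the default 12-implant roster
#'   (durations 3-12 days, footprints straddling 100,000 km2)
#' @param config a \code{\link{blocking_config}} defining qualification
#' @return list: \code{heights}, \code{dates}, \code{grid}, \code{config},
#'   \code{truth} (implant table with \code{qualifies}, per-cell
#'   \code{day_count}, \code{eval_year})
#' @export
gen_blocking_scenario <- function(seed, n_baseline_years = 12,
                                  implants = NULL,
                                  config = blocking_config()) {
  # 1-degree grid so a ~15-cell footprint sits near the 100,000 km2 bar.
  # The height climate is kept smooth (small seasonal amplitude, moderate
  # persistence, quiet evaluation year) so the implanted ridges are the only
  # structures that cross the 1-SD threshold and the truth roster is exact.
  cfg <- scenario_config(nlon = 25, nlat = 15, lon0 = -130, lat0 = 48,
                         dres = 1, start_year = 2000,
                         n_years = n_baseline_years + 1,
                         heights_amp = 30, heights_ar1 = 0.6,
                         eval_noise_scale = 0.02,
                         eval_start = as.Date(sprintf("%d-01-01",
                                                      2000 + n_baseline_years)))
  eval_year <- 2000 + n_baseline_years
  g <- cfg$grid
  if (is.null(implants)) {
    # qualifying: durations 5..12 over large footprints; rejected: too short
    # (3, 4 days) or footprint too small to reach the area bar
    implants <- data.frame(
      lon_lo = c(2, 8, 14, 19, 2, 8, 14, 19, 2, 8, 14, 20),
      lon_hi = c(6, 12, 18, 23, 6, 12, 18, 23, 6, 12, 18, 21),
      lat_lo = c(2, 2, 2, 2, 7, 7, 7, 7, 12, 12, 12, 12),
      lat_hi = c(5, 5, 5, 5, 10, 10, 10, 10, 14, 14, 14, 13),
      start_doy = c(100, 120, 140, 160, 180, 200, 220, 240, 130, 170, 210, 150),
      n_days = c(5, 6, 7, 8, 9, 10, 11, 12, 3, 4, 5, 7),
      amp_sd = 3)
  }
  ridge_cells <- function(r) {
    ix <- r$lon_lo:r$lon_hi
    iy <- r$lat_lo:r$lat_hi
    as.vector(outer(ix, (iy - 1) * g$nlon, "+"))
  }
  ridges <- lapply(seq_len(nrow(implants)), function(k) {
    r <- implants[k, ]
    list(cells = ridge_cells(r),
         start = as.Date(sprintf("%d-01-01", eval_year)) + r$start_doy - 1,
         n_days = r$n_days, amp_sd = r$amp_sd)
  })
  cfg$ridges <- ridges
  gw <- gen_weather(cfg, seed)
  implants$max_area_km2 <- vapply(ridges, function(r)
    sum(g$cell_area_km2[r$cells]), 0)
  implants$qualifies <- implants$n_days >= config$min_days &
    implants$max_area_km2 >= config$min_area_km2
  day_count <- integer(g$ncell)
  mon_ok <- function(d) as.integer(format(d, "%m")) %in% config$months
  for (k in which(implants$qualifies)) {
    r <- ridges[[k]]
    for (dd in seq_len(r$n_days)) {
      if (mon_ok(r$start + dd - 1))
        day_count[r$cells] <- day_count[r$cells] + 1L
    }
  }
  list(heights = gw$heights, dates = gw$dates, grid = g, config = config,
       truth = list(implants = implants, day_count = day_count,
                    eval_year = eval_year,
                    baseline_years = 2000:(eval_year - 1)))
}
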