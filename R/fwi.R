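# Canadian Fire Weather Index System: scalar (single-station) operations.
#
# The update equations are the standard published closed forms of the system
# (Van Wagner's consolidated equations with the usual FORTRAN constants).
# Month-dependent day-length factors below are the conventional mid-latitude
# tables used by Canadian agencies:
#   Le (DMC effective day length, hours) and Lf (DC day-length adjustment).
.dmc_day_length <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)
.dc_day_length <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)

#' Moisture-code state (FFMC, DMC, DC)
#'
#' @param ffmc Fine Fuel Moisture Code, in [0, 101]
#' @param dmc Duff Moisture Code, >= 0
#' @param dc Drought Code, >= 0
#' @return a \code{fwi_codes} list
#' @export
fwi_codes <- function(ffmc = 85, dmc = 6, dc = 15) {
  if (ffmc < 0 || ffmc > 101) stop("ffmc out of range [0, 101]")
  if (dmc < 0) stop("dmc must be >= 0")
  if (dc < 0) stop("dc must be >= 0")
  structure(list(ffmc = ffmc, dmc = dmc, dc = dc), class = "fwi_codes")
}

#' Single day of noon weather for the FWI System
#'
#' @param temp_c noon 2-m temperature (deg C)
#' @param rh_pct relative humidity (0-100)
#' @param wind_kmh 10-m wind speed (km/h, >= 0)
#' @param precip_mm 24-h accumulated precipitation (mm, >= 0)
#' @param date calendar date (used for the month day-length factors)
#' @return a \code{fwi_weather} list
#' @export
fwi_weather <- function(temp_c, rh_pct, wind_kmh, precip_mm, date) {
  if (rh_pct < 0 || rh_pct > 100) stop("rh_pct out of range [0, 100]")
  if (wind_kmh < 0) stop("wind_kmh must be >= 0")
  if (precip_mm < 0) stop("precip_mm must be >= 0")
  date <- as.Date(date)
  structure(list(temp_c = temp_c, rh_pct = rh_pct, wind_kmh = wind_kmh,
                 precip_mm = precip_mm, date = date), class = "fwi_weather")
}

#' Advance the three moisture codes by one day (scalar reference)
#'
#' Applies the standard daily rainfall and drying/wetting routines of the
#' Fine Fuel Moisture Code, Duff Moisture Code and Drought Code for a single
#' station-day. This is the system's defining scalar form; the grid engine
#' (\code{\link{run_fwi_grid}}) is an independent vectorized implementation
#' checked against it.
#'
#' @param prev \code{\link{fwi_codes}} for the previous day
#' @param obs \code{\link{fwi_weather}} for the current day
#' @return next-day \code{fwi_codes}
#' @export
fwi_update_codes <- function(prev, obs) {
  stopifnot(inherits(prev, "fwi_codes"), inherits(obs, "fwi_weather"))
  month <- as.POSIXlt(obs$date)$mon + 1
  fwi_codes(
    ffmc = .ffmc_scalar(prev$ffmc, obs$temp_c, obs$rh_pct, obs$wind_kmh, obs$precip_mm),
    dmc = .dmc_scalar(prev$dmc, obs$temp_c, obs$rh_pct, obs$precip_mm, month),
    dc = .dc_scalar(prev$dc, obs$temp_c, obs$precip_mm, month)
  )
}

.ffmc_scalar <- function(f0, t, h, w, p) {
  m <- 147.2 * (101 - f0) / (59.5 + f0)
  if (p > 0.5) {
    rf <- p - 0.5
    mr <- m + 42.5 * rf * exp(-100 / (251 - m)) * (1 - exp(-6.93 / rf))
    if (m > 150) mr <- mr + 0.0015 * (m - 150)^2 * sqrt(rf)
    if (mr > 250) mr <- 250
    m <- mr
  }
  ed <- 0.942 * h^0.679 + 11 * exp((h - 100) / 10) +
    0.18 * (21.1 - t) * (1 - exp(-0.115 * h))
  if (m > ed) {
    ko <- 0.424 * (1 - (h / 100)^1.7) + 0.0694 * sqrt(w) * (1 - (h / 100)^8)
    kd <- ko * 0.581 * exp(0.0365 * t)
    m <- ed + (m - ed) * 10^(-kd)
  } else {
    ew <- 0.618 * h^0.753 + 10 * exp((h - 100) / 10) +
      0.18 * (21.1 - t) * (1 - exp(-0.115 * h))
    if (m < ew) {
      kl <- 0.424 * (1 - ((100 - h) / 100)^1.7) +
        0.0694 * sqrt(w) * (1 - ((100 - h) / 100)^8)
      kw <- kl * 0.581 * exp(0.0365 * t)
      m <- ew - (ew - m) * 10^(-kw)
    }
  }
  f <- 59.5 * (250 - m) / (147.2 + m)
  min(max(f, 0), 101)
}

.dmc_scalar <- function(p0, t, h, p, month) {
  pr <- p0
  if (p > 1.5) {
    rw <- 0.92 * p - 1.27
    wmi <- 20 + 280 / exp(0.023 * p0)
    b <- if (p0 <= 33) {
      100 / (0.5 + 0.3 * p0)
    } else if (p0 <= 65) {
      14 - 1.3 * log(p0)
    } else {
      6.2 * log(p0) - 17.2
    }
    wmr <- wmi + 1000 * rw / (48.77 + b * rw)
    pr <- max(43.43 * (5.6348 - log(wmr - 20)), 0)
  }
  tt <- max(t, -1.1)
  rk <- 1.894 * (tt + 1.1) * (100 - h) * .dmc_day_length[month] * 1e-4
  max(pr + rk, 0)
}

.dc_scalar <- function(d0, t, p, month) {
  dr <- d0
  if (p > 2.8) {
    rd <- 0.83 * p - 1.27
    smi <- 800 * exp(-d0 / 400)
    dr <- max(d0 - 400 * log(1 + 3.937 * rd / smi), 0)
  }
  tt <- max(t, -2.8)
  pe <- (0.36 * (tt + 2.8) + .dc_day_length[month]) / 2
  if (pe < 0) pe <- 0
  dr + pe
}

#' Fire-behaviour indices from codes and wind (scalar reference)
#'
#' Computes the Initial Spread Index, Buildup Index and Fire Weather Index
#' from a day's moisture codes and wind speed using the standard closed
#' forms.
#'
#' @param codes \code{\link{fwi_codes}}
#' @param wind_kmh wind speed (km/h, >= 0)
#' @return list with \code{isi}, \code{bui}, \code{fwi}
#' @export
fwi_indices <- function(codes, wind_kmh) {
  stopifnot(inherits(codes, "fwi_codes"))
  if (wind_kmh < 0) stop("wind_kmh must be >= 0")
  m <- 147.2 * (101 - codes$ffmc) / (59.5 + codes$ffmc)
  ff <- 91.9 * exp(-0.1386 * m) * (1 + m^5.31 / 4.93e7)
  isi <- 0.208 * exp(0.05039 * wind_kmh) * ff
  dmc <- codes$dmc
  dc <- codes$dc
  bui <- if (dmc == 0 && dc == 0) {
    0
  } else if (dmc <= 0.4 * dc) {
    0.8 * dmc * dc / (dmc + 0.4 * dc)
  } else {
    dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) * (0.92 + (0.0114 * dmc)^1.7)
  }
  bui <- max(bui, 0)
  fd <- if (bui <= 80) 0.626 * bui^0.809 + 2 else 1000 / (25 + 108.64 * exp(-0.023 * bui))
  bb <- 0.1 * isi * fd
  fwi <- if (bb > 1) exp(2.72 * (0.434 * log(bb))^0.647) else bb
  list(isi = isi, bui = bui, fwi = fwi)
}

#' Fire-season startup/shutdown rules
#'
#' The fire season at a cell starts the day after its daily maximum
#' temperature has exceeded \code{start_temp_c} for \code{run_days}
#' consecutive days, and shuts down the day after it has fallen below
#' \code{stop_temp_c} for \code{run_days} consecutive days.
#'
#' @param start_temp_c startup threshold (deg C), default 12
#' @param stop_temp_c shutdown threshold (deg C), default 5
#' @param run_days consecutive days required, default 3
#' @return a \code{season_rules} list
#' @export
season_rules <- function(start_temp_c = 12, stop_temp_c = 5, run_days = 3) {
  if (run_days < 1) stop("run_days must be >= 1")
  if (start_temp_c <= stop_temp_c) stop("start_temp_c must exceed stop_temp_c")
  structure(list(start_temp_c = start_temp_c, stop_temp_c = stop_temp_c,
                 run_days = run_days), class = "season_rules")
}

#' Fire-season activity mask from a daily maximum-temperature series
#'
#' @param tmax_series numeric vector (one cell) or cell-by-day matrix of
#'   daily maximum temperature
#' @param rules a \code{\link{season_rules}}
#' @return logical vector/matrix of the same shape: TRUE where the fire
#'   season is active
#' @export
season_mask <- function(tmax_series, rules = season_rules()) {
  stopifnot(inherits(rules, "season_rules"))
  x <- if (is.matrix(tmax_series)) tmax_series else matrix(tmax_series, nrow = 1)
  nd <- ncol(x)
  if (nd < rules$run_days) {
    warning("series shorter than run_days; season never starts")
    out <- matrix(FALSE, nrow(x), nd)
    return(if (is.matrix(tmax_series)) out else as.vector(out))
  }
  nc <- nrow(x)
  active <- rep(FALSE, nc)
  run_up <- integer(nc)
  run_dn <- integer(nc)
  out <- matrix(FALSE, nc, nd)
  for (d in seq_len(nd)) {
    out[, d] <- active
    warm <- x[, d] > rules$start_temp_c
    cold <- x[, d] < rules$stop_temp_c
    run_up <- ifelse(warm, run_up + 1L, 0L)
    run_dn <- ifelse(cold, run_dn + 1L, 0L)
    active <- ifelse(!active & run_up >= rules$run_days, TRUE, active)
    active <- ifelse(active & run_dn >= rules$run_days, FALSE, active)
  }
  if (is.matrix(tmax_series)) out else as.vector(out)
}

#' Overwinter the Drought Code
#'
#' Carries the fall Drought Code moisture deficit through winter
#' precipitation to obtain the spring startup value, using the
#' moisture-equivalent form \eqn{Q_{spring} = a Q_{fall} + b\,(3.94\,r_w)}
#' with \eqn{Q = 800 e^{-DC/400}} and \eqn{DC = 400 \ln(800/Q)}, clamped at 0.
#' \code{a} is the fall-moisture carryover fraction and \code{b} the
#' effectiveness of winter precipitation \code{r_w} (mm) at recharging the
#' deep organic layer.
#'
#' @param fall_dc Drought Code at season shutdown (>= 0); vectorized
#' @param winter_precip_mm total precipitation between shutdown and startup
#' @param a carryover fraction in [0, 1]
#' @param b precipitation effectiveness in [0, 1]
#' @return spring startup Drought Code (>= 0)
#' @export
overwinter_dc <- function(fall_dc, winter_precip_mm, a = 0.75, b = 0.75) {
  if (a < 0 || a > 1 || b < 0 || b > 1) stop("a and b must lie in [0, 1]")
  if (any(fall_dc < 0)) stop("fall_dc must be >= 0")
  if (any(winter_precip_mm < 0)) stop("winter_precip_mm must be >= 0")
  qf <- 800 * exp(-fall_dc / 400)
  qs <- pmax(a * qf + b * 3.94 * winter_precip_mm, .Machine$double.eps)
  pmax(400 * log(800 / qs), 0)
}
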