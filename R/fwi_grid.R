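# Vectorized FWI System grid engine. The per-day update below is written as
# whole-grid vector arithmetic (branching via ifelse/pmin/pmax) and is kept
# deliberately separate from the scalar station forms in fwi.R; the test
# suite requires the two paths to agree to 1e-9 per cell-day.

.v_ffmc <- function(f0, t, h, w, p) {
  m <- 147.2 * (101 - f0) / (59.5 + f0)
  rf <- pmax(p - 0.5, 1e-12)
  mr <- m + 42.5 * rf * exp(-100 / (251 - m)) * (1 - exp(-6.93 / rf)) +
    ifelse(m > 150, 0.0015 * (m - 150)^2 * sqrt(rf), 0)
  m <- ifelse(p > 0.5, pmin(mr, 250), m)
  ed <- 0.942 * h^0.679 + 11 * exp((h - 100) / 10) +
    0.18 * (21.1 - t) * (1 - exp(-0.115 * h))
  ew <- 0.618 * h^0.753 + 10 * exp((h - 100) / 10) +
    0.18 * (21.1 - t) * (1 - exp(-0.115 * h))
  kd <- (0.424 * (1 - (h / 100)^1.7) + 0.0694 * sqrt(w) * (1 - (h / 100)^8)) *
    0.581 * exp(0.0365 * t)
  kw <- (0.424 * (1 - ((100 - h) / 100)^1.7) +
           0.0694 * sqrt(w) * (1 - ((100 - h) / 100)^8)) * 0.581 * exp(0.0365 * t)
  m_new <- ifelse(m > ed, ed + (m - ed) * 10^(-kd),
                  ifelse(m < ew, ew - (ew - m) * 10^(-kw), m))
  pmin(pmax(59.5 * (250 - m_new) / (147.2 + m_new), 0), 101)
}

.v_dmc <- function(p0, t, h, p, el) {
  rw <- pmax(0.92 * p - 1.27, 1e-12)
  wmi <- 20 + 280 / exp(0.023 * p0)
  b <- ifelse(p0 <= 33, 100 / (0.5 + 0.3 * p0),
              ifelse(p0 <= 65, 14 - 1.3 * log(pmax(p0, 1e-12)),
                     6.2 * log(pmax(p0, 1e-12)) - 17.2))
  wmr <- wmi + 1000 * rw / (48.77 + b * rw)
  pr <- pmax(43.43 * (5.6348 - log(wmr - 20)), 0)
  base <- ifelse(p > 1.5, pr, p0)
  rk <- 1.894 * (pmax(t, -1.1) + 1.1) * (100 - h) * el * 1e-4
  pmax(base + rk, 0)
}

.v_dc <- function(d0, t, p, fl) {
  rd <- pmax(0.83 * p - 1.27, 0)
  smi <- 800 * exp(-d0 / 400)
  dr <- pmax(d0 - 400 * log(1 + 3.937 * rd / smi), 0)
  base <- ifelse(p > 2.8, dr, d0)
  pe <- pmax((0.36 * (pmax(t, -2.8) + 2.8) + fl) / 2, 0)
  base + pe
}

.v_indices <- function(ffmc, dmc, dc, w) {
  m <- 147.2 * (101 - ffmc) / (59.5 + ffmc)
  ff <- 91.9 * exp(-0.1386 * m) * (1 + m^5.31 / 4.93e7)
  isi <- 0.208 * exp(0.05039 * w) * ff
  denom <- dmc + 0.4 * dc
  bui <- ifelse(denom <= 0, 0,
                ifelse(dmc <= 0.4 * dc, 0.8 * dmc * dc / denom,
                       dmc - (1 - 0.8 * dc / denom) *
                         (0.92 + (0.0114 * dmc)^1.7)))
  bui <- pmax(bui, 0)
  fd <- ifelse(bui <= 80, 0.626 * bui^0.809 + 2,
               1000 / (25 + 108.64 * exp(-0.023 * bui)))
  bb <- 0.1 * isi * fd
  fwi <- ifelse(bb > 1, exp(2.72 * (0.434 * log(pmax(bb, 1e-300)))^0.647), bb)
  list(isi = isi, bui = bui, fwi = fwi)
}

#' Run the FWI System over a weather grid
#'
#' Computes daily moisture codes and fire-behaviour indices for every grid
#' cell, with per-cell fire-season startup/shutdown (see
#' \code{\link{season_mask}}) and Drought Code overwintering between seasons
#' (see \code{\link{overwinter_dc}}). Each cell's trajectory depends only on
#' that cell's weather series.
#'
#' On a cell's first active day the codes are initialized to
#' \code{startup_codes} (the Drought Code replaced by the overwintered value
#' when the cell has a previous shutdown on record, with precipitation
#' accumulated over the inactive gap) and then advanced with that day's
#' weather. While a cell is inactive the codes are held at their last value
#' and the indices are missing (\code{NA}), so off-season days never enter
#' percentile climatologies.
#'
#' @param weather a \code{\link{weather_grid}}
#' @param rules \code{\link{season_rules}}
#' @param overwinter list with carryover fractions \code{a}, \code{b}
#'   (see \code{\link{overwinter_dc}})
#' @param startup_codes \code{\link{fwi_codes}} used at season startup when no
#'   overwinter history exists (conventional agency defaults
#'   FFMC 85, DMC 6, DC 15)
#' @return an object of class \code{fwi_fields}: cell-by-day matrices
#'   \code{ffmc}, \code{dmc}, \code{dc}, \code{isi}, \code{bui}, \code{fwi},
#'   logical \code{active}, plus \code{dates} and \code{grid}
#' @export
run_fwi_grid <- function(weather, rules = season_rules(),
                         overwinter = list(a = 0.75, b = 0.75),
                         startup_codes = fwi_codes()) {
  stopifnot(inherits(weather, "weather_grid"))
  nc <- weather$grid$ncell
  nd <- length(weather$dates)
  months <- as.POSIXlt(weather$dates)$mon + 1
  active <- season_mask(weather$tmax_c, rules)
  if (!is.matrix(active)) active <- matrix(active, nrow = nc)

  ffmc <- matrix(NA_real_, nc, nd)
  dmc <- matrix(NA_real_, nc, nd)
  dc <- matrix(NA_real_, nc, nd)
  isi <- matrix(NA_real_, nc, nd)
  bui <- matrix(NA_real_, nc, nd)
  fwi <- matrix(NA_real_, nc, nd)

  cur_f <- rep(NA_real_, nc)
  cur_p <- rep(NA_real_, nc)
  cur_d <- rep(NA_real_, nc)
  fall_dc <- rep(NA_real_, nc)       # DC recorded at last shutdown
  winter_precip <- rep(0, nc)        # precip accumulated while inactive
  prev_active <- rep(FALSE, nc)

  for (day in seq_len(nd)) {
    act <- active[, day]
    starting <- act & !prev_active
    stopping <- !act & prev_active
    if (any(stopping)) {
      fall_dc[stopping] <- cur_d[stopping]
      winter_precip[stopping] <- 0
    }
    if (any(starting)) {
      cur_f[starting] <- startup_codes$ffmc
      cur_p[starting] <- startup_codes$dmc
      ow <- starting & !is.na(fall_dc)
      fresh <- starting & is.na(fall_dc)
      if (any(ow))
        cur_d[ow] <- overwinter_dc(fall_dc[ow], winter_precip[ow],
                                   overwinter$a, overwinter$b)
      if (any(fresh)) cur_d[fresh] <- startup_codes$dc
    }
    if (any(!act)) {
      winter_precip[!act] <- winter_precip[!act] + weather$precip_mm[!act, day]
    }
    if (any(act)) {
      t <- weather$temp_c[act, day]
      h <- weather$rh_pct[act, day]
      w <- weather$wind_kmh[act, day]
      p <- weather$precip_mm[act, day]
      cur_f[act] <- .v_ffmc(cur_f[act], t, h, w, p)
      cur_p[act] <- .v_dmc(cur_p[act], t, h, p, .dmc_day_length[months[day]])
      cur_d[act] <- .v_dc(cur_d[act], t, p, .dc_day_length[months[day]])
      idx <- .v_indices(cur_f[act], cur_p[act], cur_d[act], w)
      ffmc[act, day] <- cur_f[act]
      dmc[act, day] <- cur_p[act]
      dc[act, day] <- cur_d[act]
      isi[act, day] <- idx$isi
      bui[act, day] <- idx$bui
      fwi[act, day] <- idx$fwi
    }
    prev_active <- act
  }
  structure(list(ffmc = ffmc, dmc = dmc, dc = dc, isi = isi, bui = bui,
                 fwi = fwi, active = active, dates = weather$dates,
                 grid = weather$grid),
            class = "fwi_fields")
}

#' @export
print.fwi_fields <- function(x, ...) {
  cat(sprintf("<fwi_fields> %d cells x %d days; %.1f%% cell-days in season\n",
              nrow(x$fwi), ncol(x$fwi), 100 * mean(x$active)))
  invisible(x)
}
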