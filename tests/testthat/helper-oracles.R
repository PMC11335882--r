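# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (loops, brute-force scans, direct formula evaluation)
# and must never call the code paths they check.

# Scalar replay of the full FWI chain for one cell: season mask, startup
# defaults, Drought Code overwintering, daily update, indices. Uses the
# package's scalar station operations, which the vectorized grid engine must
# reproduce exactly.
oracle_fwi_cell <- function(temp, rh, wind, precip, tmax, dates,
                            rules = season_rules(),
                            overwinter = list(a = 0.75, b = 0.75),
                            startup = fwi_codes()) {
  act <- season_mask(tmax, rules)
  n <- length(dates)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("ffmc", "dmc", "dc", "isi", "bui", "fwi")))
  codes <- NULL; fall <- NA_real_; wp <- 0; prev <- FALSE
  for (d in seq_len(n)) {
    a <- act[d]
    if (!a && prev) { fall <- codes$dc; wp <- 0 }
    if (a && !prev) {
      dc0 <- if (!is.na(fall)) overwinter_dc(fall, wp, overwinter$a,
                                             overwinter$b) else startup$dc
      codes <- fwi_codes(startup$ffmc, startup$dmc, dc0)
    }
    if (!a) wp <- wp + precip[d]
    if (a) {
      codes <- fwi_update_codes(codes, fwi_weather(temp[d], rh[d], wind[d],
                                                   precip[d], dates[d]))
      idx <- fwi_indices(codes, wind[d])
      out[d, ] <- c(codes$ffmc, codes$dmc, codes$dc, idx$isi, idx$bui,
                    idx$fwi)
    }
    prev <- a
  }
  list(values = out, active = act)
}

# Random valid weather matrices for property tests.
random_weather <- function(ncell, ndays, seed, start = "2021-05-01",
                           warm = TRUE) {
  set.seed(seed)
  dates <- seq(as.Date(start), by = 1, length.out = ndays)
  temp <- matrix(stats::runif(ncell * ndays, if (warm) 5 else -20, 32),
                 ncell, ndays)
  rh <- matrix(stats::runif(ncell * ndays, 5, 100), ncell, ndays)
  wind <- matrix(stats::runif(ncell * ndays, 0, 50), ncell, ndays)
  precip <- matrix(ifelse(stats::runif(ncell * ndays) < 0.3,
                          stats::rgamma(ncell * ndays, 0.7, scale = 6), 0),
                   ncell, ndays)
  tmax <- temp + 4
  list(temp = temp, rh = rh, wind = wind, precip = precip, tmax = tmax,
       dates = dates)
}

# Spearman rank correlation via explicit midranks + the Pearson formula.
brute_spearman <- function(x, y) {
  # mean position of tied values in the sorted order
  midrank <- function(v) sapply(v, function(vi) mean(which(sort(v) == vi)))
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Quantile by explicit linear interpolation between order statistics
# (type-7 definition, written out).
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# First day of the longest snow-free run, by explicit run enumeration.
brute_melt <- function(snow) {
  best_len <- 0; best_start <- NA_integer_
  d <- 1; n <- length(snow)
  while (d <= n) {
    if (!snow[d]) {
      s <- d
      while (d <= n && !snow[d]) d <- d + 1
      if ((d - s) > best_len) { best_len <- d - s; best_start <- s }
    } else d <- d + 1
  }
  best_start
}

# Maximum drying over every admissible window, by explicit scan.
brute_drying <- function(x, dates, window, start, end) {
  best <- -Inf; best_t <- NA
  for (t in seq_along(dates)) {
    if (dates[t] < start) next
    if (dates[t] + window > end) next
    if (t + window > length(x)) next
    drop <- x[t] - x[t + window]
    if (drop > best) { best <- drop; best_t <- t }
  }
  list(max_drying = max(best, 0), mid_date = dates[best_t] + window / 2)
}

# Saturation vapor pressure, improved Magnus constants, written directly.
brute_vpd <- function(t, td) {
  6.1094 * exp(17.625 * t / (243.04 + t)) -
    6.1094 * exp(17.625 * td / (243.04 + td))
}

# Pixel mask of discs around points, written independently of the package's
# rasterizer: full double loop over pixel centres.
brute_disc_mask <- function(frame, px, py, r) {
  m <- matrix(FALSE, frame$ny, frame$nx)
  for (ix in seq_len(frame$nx)) for (iy in seq_len(frame$ny)) {
    x <- frame$xmin + (ix - 1) * frame$res
    y <- frame$ymin + (iy - 1) * frame$res
    if (any((x - px)^2 + (y - py)^2 <= r^2)) m[iy, ix] <- TRUE
  }
  m
}
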