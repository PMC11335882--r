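# Baseline climatologies and extreme-fire-weather statistics: per-cell FWI95
# fields, extreme-day flags/anomalies, daily forested-extent series,
# standardized anomalies, seasonal anomalies/ranks, VPD, and the
# extent-vs-burn rank correlation.

#' Vapor pressure deficit from temperature and dewpoint
#'
#' Saturation vapor pressure uses the improved Magnus form over water,
#' \eqn{e_s(T) = 6.1094 \exp(17.625 T / (243.04 + T))} hPa; VPD is
#' \eqn{e_s(T) - e_s(T_d)}. Dewpoints above the air temperature
#' (supersaturation artifacts in reanalysis-style inputs) are clamped to the
#' temperature with a warning, giving VPD = 0.
#'
#' @param temp_c 2-m temperature (deg C); vectorized
#' @param dewpoint_c 2-m dewpoint temperature (deg C)
#' @return vapor pressure deficit (hPa), >= 0
#' @export
vpd_from_t_td <- function(temp_c, dewpoint_c) {
  if (any(dewpoint_c > temp_c, na.rm = TRUE)) {
    warning("dewpoint above temperature; clamped (VPD = 0)")
    dewpoint_c <- pmin(dewpoint_c, temp_c)
  }
  es <- function(t) 6.1094 * exp(17.625 * t / (243.04 + t))
  es(temp_c) - es(dewpoint_c)
}

#' Forest mask from canopy cover
#'
#' @param canopy_cover per-cell canopy-cover fraction in [0, 1]
#' @param threshold cover fraction above which a cell counts as forested
#'   (default 0.20)
#' @return logical vector: TRUE where cover strictly exceeds the threshold
#' @export
forest_mask <- function(canopy_cover, threshold = 0.20) {
  stopifnot(all(canopy_cover >= 0 & canopy_cover <= 1, na.rm = TRUE))
  canopy_cover > threshold
}

#' Per-cell baseline percentile of an in-season index (FWI95 and kin)
#'
#' Computes, for each cell, the \code{q} quantile of the index over all
#' in-season days in the baseline years; off-season values never contribute.
#' Quantiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7). Cells with fewer than \code{min_days}
#' contributing days are masked (\code{NA}).
#'
#' @param fwi a \code{fwi_fields} object (or any list with a cell-by-day
#'   \code{index} matrix, logical \code{active}, and \code{dates})
#' @param baseline_years integer years forming the baseline climatology
#' @param q quantile level (default 0.95)
#' @param index which index to use (default \code{"fwi"})
#' @param min_days minimum in-season baseline days for a valid cell
#' @return object of class \code{percentile_field}: \code{q95} per cell,
#'   \code{n_days}, \code{baseline_years}, \code{q}
#' @export
percentile_field <- function(fwi, baseline_years, q = 0.95, index = "fwi",
                             min_days = 100) {
  yrs <- as.integer(format(fwi$dates, "%Y"))
  sel <- yrs %in% baseline_years
  if (!any(sel)) stop("no baseline years present in input")
  x <- fwi[[index]][, sel, drop = FALSE]
  act <- fwi$active[, sel, drop = FALSE]
  x[!act] <- NA
  n_days <- rowSums(!is.na(x))
  q95 <- rep(NA_real_, nrow(x))
  ok <- n_days >= min_days
  if (any(ok))
    q95[ok] <- apply(x[ok, , drop = FALSE], 1, stats::quantile,
                     probs = q, na.rm = TRUE, type = 7, names = FALSE)
  structure(list(q95 = q95, n_days = n_days, baseline_years = baseline_years,
                 q = q, index = index),
            class = "percentile_field")
}

#' Daily forested area exceeding the local extreme-fire-weather percentile
#'
#' For each day and region, sums the area of cells that are season-active,
#' forested, and have index values strictly above the cell's baseline
#' percentile. The proportion divides by the region's total forested area
#' (cells with a defined percentile).
#'
#' @param fwi a \code{fwi_fields}
#' @param pf a \code{\link{percentile_field}} on the same grid
#' @param forest logical per-cell forest mask
#' @param regions per-cell region labels (character/factor); single region by
#'   default
#' @param cell_area_km2 per-cell areas; defaults to the grid's spherical areas
#' @return data.frame with \code{date}, \code{region}, \code{area_km2},
#'   \code{area_ha}, \code{proportion} (denominator: the region's total
#'   forested area), \code{active_area_km2} (forested area in season that
#'   day) and \code{proportion_active} (denominator: in-season forested
#'   area; NA when nothing is in season). Under a stationary climate the
#'   long-run mean of \code{proportion_active} equals 1 - q by construction.
#' @export
extent_series <- function(fwi, pf, forest = NULL, regions = NULL,
                          cell_area_km2 = NULL) {
  nc <- nrow(fwi$fwi)
  if (length(pf$q95) != nc) stop("grids misaligned: percentile field size differs")
  if (is.null(forest)) forest <- rep(TRUE, nc)
  if (length(forest) != nc) stop("grids misaligned: forest mask size differs")
  if (is.null(regions)) regions <- rep("all", nc)
  if (is.null(cell_area_km2)) cell_area_km2 <- fwi$grid$cell_area_km2
  x <- fwi[[pf$index]]
  valid <- forest & !is.na(pf$q95)
  exceed <- sweep(x, 1, pf$q95, ">") & fwi$active
  exceed[is.na(exceed)] <- FALSE
  exceed[!valid, ] <- FALSE
  regs <- sort(unique(regions[valid]))
  out <- vector("list", length(regs))
  w <- cell_area_km2
  act <- fwi$active
  act[!valid, ] <- FALSE
  for (i in seq_along(regs)) {
    in_reg <- valid & regions == regs[i]
    total <- sum(w[in_reg])
    area <- colSums(exceed[in_reg, , drop = FALSE] * w[in_reg])
    act_area <- colSums(act[in_reg, , drop = FALSE] * w[in_reg])
    out[[i]] <- data.frame(date = fwi$dates, region = regs[i],
                           area_km2 = area, area_ha = area * 100,
                           proportion = if (total > 0) area / total else NA_real_,
                           active_area_km2 = act_area,
                           proportion_active = ifelse(act_area > 0,
                                                      area / act_area,
                                                      NA_real_),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Per-cell count of extreme fire-weather days in a year, and its anomaly
#'
#' @param fwi a \code{fwi_fields}
#' @param pf a \code{\link{percentile_field}}
#' @param year target year
#' @param baseline_years years over which the mean annual count is computed
#'   (defaults to the percentile field's baseline)
#' @return data.frame per cell: \code{count}, \code{baseline_mean},
#'   \code{anomaly}
#' @export
extreme_day_counts <- function(fwi, pf, year,
                               baseline_years = pf$baseline_years) {
  yrs <- as.integer(format(fwi$dates, "%Y"))
  x <- fwi[[pf$index]]
  exceed <- sweep(x, 1, pf$q95, ">") & fwi$active
  exceed[is.na(exceed)] <- FALSE
  count <- rowSums(exceed[, yrs == year, drop = FALSE])
  per_year <- sapply(baseline_years,
                     function(y) rowSums(exceed[, yrs == y, drop = FALSE]))
  baseline_mean <- rowMeans(per_year)
  data.frame(count = count, baseline_mean = baseline_mean,
             anomaly = count - baseline_mean)
}

#' Standardized anomaly (z-score) against a per-cell baseline sample
#'
#' @param x per-cell target values (vector)
#' @param baseline cell-by-sample matrix of baseline values (e.g. one column
#'   per baseline year)
#' @return z-scores; cells whose baseline standard deviation is zero are
#'   masked (\code{NA}) with a warning
#' @export
standardized_anomaly <- function(x, baseline) {
  stopifnot(is.matrix(baseline), length(x) == nrow(baseline))
  mu <- rowMeans(baseline)
  sd <- apply(baseline, 1, stats::sd)
  z <- (x - mu) / sd
  if (any(sd == 0, na.rm = TRUE)) {
    warning("zero baseline standard deviation; affected cells masked")
    z[sd == 0] <- NA
  }
  z
}

#' Seasonal-mean anomaly and rank of a target year
#'
#' Computes, per cell, the mean of a daily field over a season window
#' (May-October by default) for every year, the target year's anomaly
#' relative to the baseline-period mean, and the target year's rank among all
#' evaluation years (rank 1 = most extreme). For variables where dry/low is
#' extreme (precipitation), set \code{direction = "low"}.
#'
#' @param values cell-by-day matrix of the daily field
#' @param dates column dates
#' @param target_year year whose anomaly/rank is reported
#' @param baseline_years years defining the climatological mean
#' @param eval_years years over which the rank is computed
#' @param months season window months (default 5:10, May-October)
#' @param direction \code{"high"} (rank 1 = largest seasonal mean) or
#'   \code{"low"} (rank 1 = smallest)
#' @return list with per-cell \code{anomaly}, \code{rank}, and the
#'   cell-by-year matrix of \code{seasonal_means}
#' @export
season_anomaly_rank <- function(values, dates, target_year, baseline_years,
                                eval_years, months = 5:10,
                                direction = c("high", "low")) {
  direction <- match.arg(direction)
  yrs <- as.integer(format(dates, "%Y"))
  mon <- as.integer(format(dates, "%m"))
  need <- sort(unique(c(target_year, baseline_years, eval_years)))
  missing_years <- setdiff(need, unique(yrs[mon %in% months]))
  if (length(missing_years))
    stop("missing years in input: ", paste(missing_years, collapse = ", "))
  sm <- sapply(need, function(y)
    rowMeans(values[, yrs == y & mon %in% months, drop = FALSE]))
  colnames(sm) <- need
  base_mean <- rowMeans(sm[, as.character(baseline_years), drop = FALSE])
  anomaly <- sm[, as.character(target_year)] - base_mean
  ev <- sm[, as.character(eval_years), drop = FALSE]
  tgt <- sm[, as.character(target_year)]
  rank1 <- if (direction == "high") {
    rowSums(ev > tgt) + 1L
  } else {
    rowSums(ev < tgt) + 1L
  }
  list(anomaly = anomaly, rank = rank1, seasonal_means = sm)
}

#' Spearman correlation between extreme-weather extent and daily area burned
#'
#' Aligns the two series on common (date, region) pairs and computes the
#' Spearman rank correlation per region (midranks for ties).
#'
#' @param extent data.frame from \code{\link{extent_series}} (columns
#'   \code{date}, \code{region}, and the extent measure)
#' @param burn data.frame with \code{date}, \code{region}, \code{area_ha}
#' @param extent_var extent column to correlate (default \code{"area_ha"})
#' @return data.frame per region: \code{rho}, \code{n}; regions with fewer
#'   than 3 paired days get \code{NA} with a warning
#' @export
correlate_extent_burn <- function(extent, burn, extent_var = "area_ha") {
  regs <- sort(unique(intersect(extent$region, burn$region)))
  res <- data.frame(region = regs, rho = NA_real_, n = 0L)
  for (i in seq_along(regs)) {
    e <- extent[extent$region == regs[i], c("date", extent_var)]
    names(e) <- c("date", "extent_value")
    b <- burn[burn$region == regs[i], c("date", "area_ha")]
    names(b) <- c("date", "burn_value")
    m <- merge(e, b, by = "date")
    res$n[i] <- nrow(m)
    if (nrow(m) < 3) {
      warning("region ", regs[i], ": fewer than 3 paired days; rho undefined")
      next
    }
    res$rho[i] <- stats::cor(m$extent_value, m$burn_value,
                             method = "spearman")
  }
  res
}
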