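# Fire-level summaries: size classes, ignition-month proportions, durations
# and potential spread days, power-law size relation, cause/response
# tabulations, and PM2.5 exceedance-day counting.

#' Size thresholds used throughout the fire-level summaries
#'
#' Large fires strictly exceed 200 ha; very large fires strictly exceed
#' 50,000 ha; ignition-month summaries use fires > 1,000 ha; day-of-burn
#' interpolation applies to fires >= 500 ha; polygons < 1 ha are dropped.
#' @export
size_thresholds <- function() {
  list(large_ha = 200, very_large_ha = 50000, growth_subset_ha = 1000,
       interp_min_ha = 500, min_polygon_ha = 1)
}

#' Validate a fire-record table
#'
#' @param records data.frame with \code{id}, \code{size_ha}, \code{start}
#'   (Date), \code{out} (Date), \code{cause} in lightning/human/unknown,
#'   \code{response} in full/modified/monitored, optional \code{region},
#'   \code{lon}, \code{lat}
#' @return the validated data.frame
#' @export
fire_records <- function(records) {
  stopifnot(all(c("id", "size_ha", "start", "out") %in% names(records)))
  if (any(records$size_ha <= 0)) stop("size_ha must be > 0")
  if (any(records$out < records$start)) stop("out date before start date")
  if (is.null(records$cause)) records$cause <- "unknown"
  records$cause[!records$cause %in% c("lightning", "human")] <- "unknown"
  if (is.null(records$response)) records$response <- "full"
  records
}

#' Counts and area proportions by fire size class
#'
#' Class boundaries are left-open: a fire belongs to class \code{(a, b]} when
#' \code{size > a} and \code{size <= b}, so a fire of exactly 200 ha is not
#' "large".
#'
#' @param records a \code{\link{fire_records}} table
#' @param breaks class boundaries in ha (default 0, 200, 1e3, 1e4, 5e4, 1e5,
#'   Inf)
#' @return data.frame per class: \code{count}, \code{count_prop},
#'   \code{area_ha}, \code{area_prop}
#' @export
size_summary <- function(records,
                         breaks = c(0, 200, 1e3, 1e4, 5e4, 1e5, Inf)) {
  cl <- cut(records$size_ha, breaks = breaks, right = TRUE)
  count <- as.integer(table(cl))
  area <- as.numeric(tapply(records$size_ha, cl, sum, default = 0))
  data.frame(class = levels(cl), count = count,
             count_prop = count / sum(count),
             area_ha = area, area_prop = area / sum(area))
}

#' Ignition-month proportions for fires above a size floor
#'
#' @param records a \code{\link{fire_records}} table
#' @param min_size_ha only fires strictly larger than this are included
#'   (default 1,000 ha)
#' @return data.frame per represented month: \code{count_prop} and
#'   \code{area_prop}, each summing to 1
#' @export
ignition_month_summary <- function(records, min_size_ha = 1000) {
  r <- records[records$size_ha > min_size_ha, ]
  if (!nrow(r)) return(data.frame(month = integer(), count_prop = numeric(),
                                  area_prop = numeric()))
  m <- as.integer(format(as.Date(r$start), "%m"))
  months <- sort(unique(m))
  count <- vapply(months, function(mm) sum(m == mm), 0L)
  area <- vapply(months, function(mm) sum(r$size_ha[m == mm]), 0)
  data.frame(month = months, count = count,
             count_prop = count / sum(count),
             area_ha = area, area_prop = area / sum(area))
}

#' Fire durations, potential spread days, and the size/spread power law
#'
#' Duration is \code{out - start + 1} days. Potential spread days count the
#' days within a fire's active interval on which any grid cell overlapping
#' its footprint exceeds that cell's extreme-fire-weather percentile. Fires
#' are split into west/east at a meridian (default -85 deg). Each side gets
#' the median duration with a 90% interval (the 5th-95th percentile of the
#' per-fire distribution), and a power law \eqn{size \propto (spread\,days +
#' 1)^\gamma} is fitted by least squares on the log scale.
#'
#' @param records a \code{\link{fire_records}} table with \code{lon}
#' @param fire_cells named list: fire id -> indices of grid cells overlapping
#'   the fire footprint
#' @param fwi a \code{fwi_fields}
#' @param pf a \code{\link{percentile_field}}
#' @param split_lon west/east split meridian (default -85)
#' @return list: \code{per_fire} (duration, spread_days, side),
#'   \code{by_side} (median and 90% interval of durations),
#'   \code{power_law} (gamma, se, intercept)
#' @export
duration_spread_analysis <- function(records, fire_cells, fwi, pf,
                                     split_lon = -85) {
  exceed <- sweep(fwi[[pf$index]], 1, pf$q95, ">") & fwi$active
  exceed[is.na(exceed)] <- FALSE
  per <- records
  per$duration <- as.integer(as.Date(per$out) - as.Date(per$start)) + 1L
  per$side <- ifelse(per$lon < split_lon, "west", "east")
  per$spread_days <- NA_integer_
  for (i in seq_len(nrow(per))) {
    cells <- fire_cells[[as.character(per$id[i])]]
    if (is.null(cells)) {
      warning("fire ", per$id[i], " has no overlapping cell; skipped")
      next
    }
    days <- which(fwi$dates >= as.Date(per$start[i]) &
                  fwi$dates <= as.Date(per$out[i]))
    sub <- exceed[cells, days, drop = FALSE]
    per$spread_days[i] <- sum(apply(sub, 2, any))
  }
  by_side <- do.call(rbind, lapply(split(per, per$side), function(s) {
    q <- stats::quantile(s$duration, c(0.05, 0.5, 0.95), type = 7,
                         names = FALSE)
    data.frame(side = s$side[1], n = nrow(s), median_duration = q[2],
               lo90 = q[1], hi90 = q[3])
  }))
  fit <- stats::lm(log(size_ha) ~ log(spread_days + 1),
                   data = per[!is.na(per$spread_days), ])
  cf <- summary(fit)$coefficients
  list(per_fire = per, by_side = by_side,
       power_law = list(gamma = cf[2, 1], se = cf[2, 2],
                        intercept = cf[1, 1]))
}

#' Tabulate fires by cause and by management response
#'
#' @param records a \code{\link{fire_records}} table
#' @param large_ha containment threshold (default 200 ha)
#' @return list: \code{by_cause} and \code{by_response} (count/area
#'   proportions), \code{containment} (per response type, the fraction of
#'   fires held below \code{large_ha})
#' @export
response_cause_summary <- function(records, large_ha = 200) {
  tab <- function(key) {
    k <- records[[key]]
    levs <- sort(unique(k))
    data.frame(level = levs,
               count = vapply(levs, function(l) sum(k == l), 0L),
               count_prop = vapply(levs, function(l) mean(k == l), 0),
               area_ha = vapply(levs, function(l) sum(records$size_ha[k == l]), 0),
               area_prop = vapply(levs, function(l)
                 sum(records$size_ha[k == l]) / sum(records$size_ha), 0))
  }
  cont <- do.call(rbind, lapply(split(records, records$response), function(s)
    data.frame(response = s$response[1], n = nrow(s),
               containment = mean(s$size_ha < large_ha))))
  list(by_cause = tab("cause"), by_response = tab("response"),
       containment = cont)
}

#' PM2.5 exceedance days and annual maximum
#'
#' @param series daily mean PM2.5 concentrations (ug m-3) at one location
#' @param threshold daily standard (default 27 ug m-3); days strictly above
#'   it are counted
#' @return list: \code{exceedance_days}, \code{annual_max}; all-missing
#'   series return NA with a warning
#' @export
pm25_exceedance <- function(series, threshold = 27) {
  if (all(is.na(series))) {
    warning("all-missing PM2.5 series")
    return(list(exceedance_days = NA_integer_, annual_max = NA_real_))
  }
  list(exceedance_days = sum(series > threshold, na.rm = TRUE),
       annual_max = max(series, na.rm = TRUE))
}
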