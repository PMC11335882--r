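# Snowmelt timing from daily binary snow-cover series and flash-drought
# statistics from root-zone soil-moisture series.

#' Snowmelt timing: first day of the longest snow-free period
#'
#' For each series (one calendar year of daily snow-covered flags) returns
#' the first day-of-year of the longest snow-free run. Ties go to the
#' earliest run; runs do not wrap across calendar years. A never snow-free
#' series returns \code{NA} (flagged with a warning); a never snow-covered
#' series returns day 1 (degenerate: snow-free all year).
#'
#' @param series logical vector of daily snow-covered flags, or a
#'   cell-by-day logical matrix
#' @return integer melt day-of-year (vector with one entry per cell)
#' @export
snowmelt_timing <- function(series) {
  x <- if (is.matrix(series)) series else matrix(series, nrow = 1)
  out <- apply(x, 1, function(s) {
    r <- rle(as.logical(s))
    free <- which(!r$values)
    if (!length(free)) return(NA_integer_)
    starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
    best <- free[which.max(r$lengths[free])]   # which.max -> earliest tie
    starts[best]
  })
  if (any(is.na(out))) warning("never snow-free cell(s): melt day undefined")
  as.integer(out)
}

#' Snowmelt-timing departure from a baseline mean
#'
#' @param melt per-cell melt day-of-year for the target year
#' @param baseline cell-by-year matrix of baseline melt days
#' @return departure in days (negative = earlier melt than baseline);
#'   cells with missing baseline are masked
#' @export
melt_departure <- function(melt, baseline) {
  stopifnot(is.matrix(baseline), length(melt) == nrow(baseline))
  melt - rowMeans(baseline)
}

#' Maximum drying of root-zone soil moisture over a sliding window
#'
#' Scans windows that lie fully inside the search interval and measures
#' drying as the endpoint decrease over \code{window} days,
#' \eqn{x(t) - x(t + window)}, floored at 0 (wetting is not reported as
#' negative drying). The midpoint of the earliest maximal window is reported
#' as the timing of rapid drought onset.
#'
#' @param rzsm daily root-zone soil moisture (kg m-2) for one cell
#' @param dates dates of the series (consecutive days)
#' @param window window length in days (default 14)
#' @param search_start,search_end search interval (default May 1 - June 30 of
#'   the series' year)
#' @return list: \code{max_drying} (kg m-2), \code{mid_date} (midpoint of the
#'   earliest maximal window), \code{start_date}, \code{window_days}
#' @export
max_window_drying <- function(rzsm, dates, window = 14,
                              search_start = NULL, search_end = NULL) {
  stopifnot(length(rzsm) == length(dates))
  if (any(diff(dates) != 1)) {
    gaps <- dates[which(diff(dates) != 1)] + 1
    stop("gaps in series starting at: ", paste(gaps, collapse = ", "))
  }
  yr <- format(dates[1], "%Y")
  if (is.null(search_start)) search_start <- as.Date(paste0(yr, "-05-01"))
  if (is.null(search_end)) search_end <- as.Date(paste0(yr, "-06-30"))
  starts <- which(dates >= search_start & dates + window <= search_end)
  starts <- starts[starts + window <= length(rzsm)]
  if (!length(starts)) stop("series does not cover the search interval plus window")
  drops <- rzsm[starts] - rzsm[starts + window]
  best <- which.max(drops)   # earliest maximal window
  max_dry <- max(drops[best], 0)
  list(max_drying = max_dry,
       mid_date = dates[starts[best]] + window / 2,
       start_date = dates[starts[best]],
       window_days = window)
}

#' Grid version of \code{\link{max_window_drying}}
#'
#' @param rzsm cell-by-day matrix of root-zone soil moisture
#' @param dates column dates
#' @param ... passed to \code{\link{max_window_drying}}
#' @return data.frame per cell: \code{max_drying}, \code{mid_date},
#'   \code{start_date}
#' @export
max_window_drying_grid <- function(rzsm, dates, ...) {
  res <- lapply(seq_len(nrow(rzsm)),
                function(i) max_window_drying(rzsm[i, ], dates, ...))
  data.frame(max_drying = vapply(res, `[[`, 0, "max_drying"),
             mid_date = do.call(c, lapply(res, `[[`, "mid_date")),
             start_date = do.call(c, lapply(res, `[[`, "start_date")))
}
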