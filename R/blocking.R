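# Persistent positive anomaly (blocking proxy) detection in 500-hPa
# geopotential heights: per-cell standardization against a seasonal
# climatology, contiguous-region extraction day by day, overlap linkage into
# events, and filtering on persistence and footprint area.

#' Blocking detection configuration
#'
#' @param sd_threshold anomaly threshold in local SD units (default 1)
#' @param min_days minimum persistence in days (default 5)
#' @param min_area_km2 minimum footprint area the event must reach at some
#'   point in its evolution (default 100,000 km2)
#' @param months season window months (default 4:10, April-October)
#' @param connectivity 4 or 8 neighbour contiguity (default 8)
#' @param overlap_min minimum shared-cell count for day-to-day linkage
#'   (default 1: any shared cell)
#' @return a \code{blocking_config} list
#' @export
blocking_config <- function(sd_threshold = 1, min_days = 5,
                            min_area_km2 = 1e5, months = 4:10,
                            connectivity = 8, overlap_min = 1) {
  stopifnot(min_days >= 1, min_area_km2 > 0, connectivity %in% c(4, 8))
  structure(list(sd_threshold = sd_threshold, min_days = min_days,
                 min_area_km2 = min_area_km2, months = months,
                 connectivity = connectivity, overlap_min = overlap_min),
            class = "blocking_config")
}

#' Standardize heights against a per-cell seasonal climatology
#'
#' "Seasonal" climatology is the per-cell calendar-month mean and SD over the
#' baseline years (a 3-month centred window is available via
#' \code{smooth_months}).
#'
#' @param heights cell-by-day matrix of 500-hPa geopotential heights
#' @param dates column dates
#' @param baseline_years years defining the climatology
#' @param smooth_months if TRUE, pool each month with its two neighbours
#' @return cell-by-day z-score matrix; cells/months with zero SD are masked
#' @export
anomaly_field <- function(heights, dates, baseline_years,
                          smooth_months = FALSE) {
  yrs <- as.integer(format(dates, "%Y"))
  mon <- as.integer(format(dates, "%m"))
  if (!any(yrs %in% baseline_years)) stop("no baseline years present in input")
  z <- matrix(NA_real_, nrow(heights), ncol(heights))
  for (m in sort(unique(mon))) {
    mm <- if (smooth_months) ((m + c(-2, -1, 0)) %% 12) + 1 else m
    base <- heights[, yrs %in% baseline_years & mon %in% mm, drop = FALSE]
    mu <- rowMeans(base)
    sd <- apply(base, 1, stats::sd)
    sd[sd == 0] <- NA
    cols <- which(mon == m)
    z[, cols] <- (heights[, cols, drop = FALSE] - mu) / sd
  }
  z
}

# Connected-component labelling of a logical field on the grid, with
# configurable 4/8 connectivity (EBImage::bwlabel is fixed-connectivity).
# Label propagation: seed unique labels, then iterate minimum over the
# neighbourhood until a fixpoint. Grids here are small (weather-model scale).
.label_components <- function(flag, nlon, nlat, connectivity = 8) {
  m <- matrix(ifelse(flag, seq_along(flag), 0L), nlat, nlon, byrow = TRUE)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    old <- m
    for (s in shifts) {
      sh <- matrix(Inf, nlat, nlon)
      rs <- max(1, 1 + s[1]):min(nlat, nlat + s[1])
      cs <- max(1, 1 + s[2]):min(nlon, nlon + s[2])
      sh[rs, cs] <- m[rs - s[1], cs - s[2]]
      sh[sh == 0] <- Inf
      upd <- m > 0 & sh < m
      m[upd] <- sh[upd]
    }
    if (identical(old, m)) break
  }
  lab <- rep(0L, length(flag))
  lab[flag] <- as.integer(factor(t(m)[t(m) > 0]))
  lab
}

#' Detect persistent positive anomaly events
#'
#' Flags cells where the z-score exceeds \code{sd_threshold}, extracts
#' contiguous regions each day (within the season window), links regions on
#' consecutive days that share at least \code{overlap_min} cells (splits and
#' merges resolved by largest-overlap inheritance; other regions spawn new
#' events), and keeps events that persist at least \code{min_days} days and
#' whose footprint reaches \code{min_area_km2} at some time.
#'
#' @param z cell-by-day z-score matrix (from \code{\link{anomaly_field}})
#' @param dates column dates
#' @param grid the \code{\link{ws_grid}}
#' @param config a \code{\link{blocking_config}}
#' @return list of events; each has \code{start}, \code{end}, \code{duration},
#'   \code{max_area_km2}, \code{area_km2} (per day), \code{cells} (list of
#'   per-day member cell indices), \code{days} (column indices)
#' @export
detect_events <- function(z, dates, grid, config = blocking_config()) {
  mon <- as.integer(format(dates, "%m"))
  in_window <- mon %in% config$months
  events <- list()
  open <- list()   # id -> list(cells_yesterday, event index)
  close_all <- function(open) list()
  for (d in seq_len(ncol(z))) {
    if (!in_window[d]) { open <- close_all(open); next }
    flag <- !is.na(z[, d]) & z[, d] > config$sd_threshold
    if (!any(flag)) { open <- close_all(open); next }
    lab <- .label_components(flag, grid$nlon, grid$nlat, config$connectivity)
    comp_cells <- split(which(lab > 0), lab[lab > 0])
    n_comp <- length(comp_cells)
    # overlap table between open events and today's components
    links <- NULL
    if (length(open)) {
      for (ei in seq_along(open)) for (ci in seq_len(n_comp)) {
        ov <- length(intersect(open[[ei]]$cells, comp_cells[[ci]]))
        if (ov >= config$overlap_min)
          links <- rbind(links, c(ei, ci, ov))
      }
    }
    assigned_comp <- rep(NA_integer_, n_comp)
    used_event <- rep(FALSE, length(open))
    if (!is.null(links)) {
      links <- links[order(-links[, 3], links[, 1], links[, 2]), , drop = FALSE]
      for (r in seq_len(nrow(links))) {
        ei <- links[r, 1]; ci <- links[r, 2]
        if (!used_event[ei] && is.na(assigned_comp[ci])) {
          assigned_comp[ci] <- open[[ei]]$idx
          used_event[ei] <- TRUE
        }
      }
    }
    new_open <- list()
    for (ci in seq_len(n_comp)) {
      cells <- comp_cells[[ci]]
      area <- sum(grid$cell_area_km2[cells])
      if (is.na(assigned_comp[ci])) {
        events[[length(events) + 1]] <- list(
          days = d, cells = list(cells), area_km2 = area)
        idx <- length(events)
      } else {
        idx <- assigned_comp[ci]
        events[[idx]]$days <- c(events[[idx]]$days, d)
        events[[idx]]$cells <- c(events[[idx]]$cells, list(cells))
        events[[idx]]$area_km2 <- c(events[[idx]]$area_km2, area)
      }
      new_open[[length(new_open) + 1]] <- list(cells = cells, idx = idx)
    }
    open <- new_open
  }
  keep <- list()
  for (ev in events) {
    duration <- length(ev$days)
    max_area <- max(ev$area_km2)
    if (duration >= config$min_days && max_area >= config$min_area_km2) {
      keep[[length(keep) + 1]] <- list(
        start = dates[ev$days[1]], end = dates[ev$days[duration]],
        duration = duration, max_area_km2 = max_area,
        area_km2 = ev$area_km2, cells = ev$cells, days = ev$days)
    }
  }
  keep
}

#' Per-cell count of blocking days
#'
#' Sums, at each cell, the days (within the season window) on which any
#' qualifying persistent-positive-anomaly event covers the cell.
#'
#' @param events list from \code{\link{detect_events}}
#' @param grid the \code{\link{ws_grid}}
#' @param dates the date vector the events were detected on
#' @param months season window months (default 4:10)
#' @return integer per-cell count of blocking days
#' @export
blocking_day_map <- function(events, grid, dates, months = 4:10) {
  count <- integer(grid$ncell)
  mon <- as.integer(format(dates, "%m"))
  for (ev in events) {
    for (i in seq_along(ev$days)) {
      if (mon[ev$days[i]] %in% months)
        count[ev$cells[[i]]] <- count[ev$cells[[i]]] + 1L
    }
  }
  count
}
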