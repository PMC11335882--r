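# Day-of-burn interpolation: hotspot time correction and filtering, ordinary
# kriging of detection dates to a pixel grid clipped to the fire perimeter,
# and daily area-burned series. The geostatistics (empirical variogram,
# exponential/spherical/gaussian models, ordinary-kriging system) are
# implemented here directly.

#' Kriging configuration for day-of-burn interpolation
#'
#' @param model variogram family: exponential (default), spherical, gaussian
#' @param nugget,sill,range optional fixed variogram parameters; if NULL they
#'   are fitted per fire to the empirical variogram of detection dates
#' @param max_points if the number of hotspots exceeds this, a random
#'   subsample of this size is used for the kriging system (keeps the linear
#'   solve bounded); default 2500
#' @return a \code{kriging_config} list
#' @export
kriging_config <- function(model = c("exponential", "spherical", "gaussian"),
                           nugget = NULL, sill = NULL, range = NULL,
                           max_points = 2500) {
  model <- match.arg(model)
  if (!is.null(nugget) && nugget < 0) stop("nugget must be >= 0")
  if (!is.null(sill) && !is.null(nugget) && sill < nugget)
    stop("sill must be >= nugget")
  if (!is.null(range) && range <= 0) stop("range must be > 0")
  structure(list(model = model, nugget = nugget, sill = sill, range = range,
                 max_points = max_points), class = "kriging_config")
}

#' Filter and time-correct hotspot detections
#'
#' Converts UTC acquisition times to local standard time using the
#' longitude-band offset \code{round(lon / 15)} hours, derives the local
#' detection date, and removes detections before the season start
#' (April 1 by default) as false off-season detections.
#'
#' @param hotspots data.frame with \code{lon} and \code{acq_datetime}
#'   (POSIXct, UTC); other columns carried through
#' @param season_start Date before which detections are dropped
#' @return the filtered data.frame with added \code{local_datetime},
#'   \code{local_date}
#' @export
prepare_hotspots <- function(hotspots, season_start = NULL) {
  stopifnot(!is.null(hotspots$lon), !is.null(hotspots$acq_datetime))
  off_h <- round(hotspots$lon / 15)
  local <- hotspots$acq_datetime + off_h * 3600
  hotspots$local_datetime <- local
  hotspots$local_date <- as.Date(local, tz = "UTC")
  if (is.null(season_start)) {
    yr <- format(min(hotspots$local_date), "%Y")
    season_start <- as.Date(paste0(yr, "-04-01"))
  }
  hotspots[hotspots$local_date >= season_start, , drop = FALSE]
}

.vgm_value <- function(h, model, nugget, psill, range) {
  g <- switch(model,
    exponential = psill * (1 - exp(-h / range)),
    spherical = ifelse(h < range,
                       psill * (1.5 * h / range - 0.5 * (h / range)^3), psill),
    gaussian = psill * (1 - exp(-(h / range)^2)))
  ifelse(h > 0, nugget + g, 0)
}

# Empirical semivariogram (equal-width distance bins to cutoff) and weighted
# least-squares fit of (nugget, partial sill, range).
.fit_variogram <- function(coords, vals, model, nbins = 15, cutoff = NULL) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  if (is.null(cutoff)) cutoff <- max(d) / 2
  iu <- which(upper.tri(d) & d <= cutoff & d > 0)
  dv <- d[iu]
  gv <- 0.5 * (outer(vals, vals, "-")^2)[iu]
  bins <- cut(dv, breaks = seq(0, cutoff, length.out = nbins + 1))
  bh <- tapply(dv, bins, mean)
  bg <- tapply(gv, bins, mean)
  bn <- tapply(gv, bins, length)
  ok <- !is.na(bg)
  bh <- bh[ok]; bg <- bg[ok]; bn <- bn[ok]
  v <- stats::var(vals)
  obj <- function(p) {
    th <- exp(p)
    pred <- .vgm_value(bh, model, th[1], th[2], th[3])
    sum(bn * (bg - pred)^2)
  }
  fit <- stats::optim(log(c(max(v * 0.05, 1e-6), max(v, 1e-6), cutoff / 3)),
                      obj, method = "Nelder-Mead",
                      control = list(maxit = 500))
  th <- exp(fit$par)
  list(nugget = th[1], psill = th[2], range = th[3])
}

# Ordinary kriging predictor. Builds the (n+1) system with a Lagrange
# multiplier once, then solves for all prediction locations in chunks.
.ok_predict <- function(coords, vals, pred, model, nugget, psill, range) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  G <- .vgm_value(D, model, nugget, psill, range)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  # tiny ridge on the diagonal for numerical safety with clustered points
  diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-9
  Ainv <- solve(A)
  out <- numeric(nrow(pred))
  chunk <- 2000L
  for (s in seq(1, nrow(pred), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pred))
    px <- pred[s:e, 1]; py <- pred[s:e, 2]
    Dp <- sqrt(outer(coords[, 1], px, function(a, b) (a - b)^2) +
               outer(coords[, 2], py, function(a, b) (a - b)^2))
    B <- rbind(.vgm_value(Dp, model, nugget, psill, range), 1)
    W <- Ainv %*% B
    out[s:e] <- colSums(W[seq_len(n), , drop = FALSE] * vals)
  }
  out
}

#' Interpolate hotspot detection dates to a per-pixel day-of-burn grid
#'
#' Ordinary kriging of detection dates (as continuous day ordinals) over the
#' pixels of a fire's perimeter mask. Predictions are clamped to the fire's
#' observed date range and rounded half-up to whole days. With fewer than 5
#' hotspots the method falls back to nearest-neighbour date assignment
#' (flagged in the result). Duplicate hotspot locations are collapsed to
#' their mean date before solving.
#'
#' @param hotspots prepared hotspots for one fire: data.frame with projected
#'   \code{x}, \code{y} (m) and \code{local_datetime} (or \code{local_date})
#' @param fire one fire entry of a \code{perimeter_set} (list with
#'   \code{frame}, \code{ids}), the perimeter the grid is clipped to
#' @param config a \code{\link{kriging_config}}
#' @param seed seed for the subsample draw when hotspots exceed
#'   \code{max_points}
#' @return object of class \code{burn_date_grid}: \code{frame}, \code{ids},
#'   \code{day} (integer ordinal day per pixel), \code{origin} (Date of day
#'   0), \code{fire_id}, \code{method}, \code{variogram}
#' @export
krige_burn_dates <- function(hotspots, fire, config = kriging_config(),
                             seed = 1L) {
  tvals <- if (!is.null(hotspots$local_datetime))
    as.numeric(hotspots$local_datetime) / 86400 else
    as.numeric(hotspots$local_date)
  origin <- as.Date("1970-01-01")
  xy <- cbind(hotspots$x, hotspots$y)
  pred <- as.matrix(frame_coords(fire$frame, fire$ids))
  lo <- floor(min(tvals)); hi <- floor(max(tvals))
  if (nrow(xy) < 5) {
    warning("fewer than 5 hotspots; nearest-neighbour fallback")
    nn <- apply(pred, 1, function(p)
      which.min((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2))
    day <- floor(tvals[nn])
    return(structure(list(frame = fire$frame, ids = fire$ids,
                          day = as.integer(pmin(pmax(day, lo), hi)),
                          origin = origin, fire_id = fire$fire_id,
                          method = "nearest", variogram = NULL),
                     class = "burn_date_grid"))
  }
  # collapse exact duplicate locations to their mean date
  key <- paste(xy[, 1], xy[, 2])
  if (anyDuplicated(key)) {
    agg <- tapply(tvals, key, mean)
    first <- !duplicated(key)
    xy <- xy[first, , drop = FALSE]
    tvals <- as.numeric(agg[key[first]])
  }
  if (nrow(xy) > config$max_points) {
    old <- .Random.seed_save()
    set.seed(seed)
    pick <- sample.int(nrow(xy), config$max_points)
    .Random.seed_restore(old)
    xy <- xy[pick, , drop = FALSE]
    tvals <- tvals[pick]
  }
  vg <- if (is.null(config$nugget) || is.null(config$sill) || is.null(config$range)) {
    f <- .fit_variogram(xy, tvals, config$model)
    list(nugget = if (is.null(config$nugget)) f$nugget else config$nugget,
         psill = f$psill, range = if (is.null(config$range)) f$range else config$range)
  } else {
    list(nugget = config$nugget, psill = config$sill - config$nugget,
         range = config$range)
  }
  z <- .ok_predict(xy, tvals, pred, config$model, vg$nugget, vg$psill, vg$range)
  day <- floor(z + 0.5)                     # round half-up to whole days
  day <- pmin(pmax(day, lo), hi)            # clamp to observed date range
  structure(list(frame = fire$frame, ids = fire$ids, day = as.integer(day),
                 origin = origin, fire_id = fire$fire_id,
                 method = "ordinary_kriging", variogram = vg),
            class = "burn_date_grid")
}

# save/restore the RNG state so internal draws do not perturb user streams
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Daily burned-area series from day-of-burn grids
#'
#' Tallies each fire's pixels by day of burn. By construction each fire's
#' daily areas sum exactly to its footprint area. Fires are assigned to
#' regions by fire id.
#'
#' @param grids list of \code{burn_date_grid} objects
#' @param regions optional named vector fire_id -> region (default "all")
#' @return data.frame: \code{region}, \code{date}, \code{area_ha} (summed
#'   over fires), plus per-fire rows in attribute \code{"per_fire"}
#' @export
daily_area_series <- function(grids, regions = NULL) {
  # overlap guard: fires sharing a frame must not share pixels
  sig <- vapply(grids, function(g)
    paste(g$frame$xmin, g$frame$ymin, g$frame$res), "")
  for (s in unique(sig)) {
    same <- which(sig == s)
    if (length(same) > 1) {
      all_ids <- unlist(lapply(grids[same], function(g) {
        xy <- frame_coords(g$frame, g$ids); paste(xy$x, xy$y)
      }))
      if (anyDuplicated(all_ids))
        stop("overlapping burn-date grids: ",
             paste(vapply(grids[same], function(g) as.character(g$fire_id), ""),
                   collapse = ", "))
    }
  }
  rows <- list()
  for (g in grids) {
    tab <- table(g$day)
    reg <- if (is.null(regions)) "all" else unname(regions[as.character(g$fire_id)])
    rows[[length(rows) + 1]] <- data.frame(
      fire_id = as.character(g$fire_id), region = reg,
      date = g$origin + as.integer(names(tab)),
      area_ha = as.numeric(tab) * g$frame$res^2 / 1e4)
  }
  per_fire <- do.call(rbind, rows)
  agg <- stats::aggregate(area_ha ~ region + date, per_fire, sum)
  agg <- agg[order(agg$region, agg$date), ]
  rownames(agg) <- NULL
  attr(agg, "per_fire") <- per_fire
  agg
}
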