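# Synthetic fire growth with known truth: daily expanding ellipses produce a
# monotone day-of-burn field; hotspots are sampled from each day's newly
# burned band; water bodies and unburned islands are carved out of the true
# burned area; reference perimeters equal the true (cleaned) burned area.

#' Generate synthetic fires, hotspots and reference perimeters
#'
#' Each fire grows as a day-indexed expanding ellipse (stochastic axis
#' increments, fixed orientation); the true burned area is the final ellipse
#' minus implanted water bodies and unburned islands. Hotspots are sampled
#' from each day's newly burned pixels at the stated density, jittered within
#' the pixel and through the afternoon overpass window, with timestamps
#' converted to UTC from local standard time. A stated number of false
#' detections is scattered before April 1, and small sliver polygons
#' (< 1 ha) are provided as buffering artifacts for the cleaning stage.
#'
#' @param fires data.frame, one row per fire: \code{id}, \code{cx}, \code{cy}
#'   (projected m), \code{lon} (for time correction and west/east splits),
#'   \code{ignition} (Date), \code{n_days}, \code{size_ha} (target final
#'   area), \code{ecozone}, \code{has_reference} (logical), \code{n_lakes},
#'   \code{n_islands}, optional \code{year}
#' @param seed integer seed; output is reproducible from (fires, seed)
#' @param res pixel size of the fire frames (m, default 180)
#' @param ha_per_hotspot sampling density (default one hotspot per 25 ha of
#'   daily growth)
#' @param aspect ellipse minor/major axis ratio
#' @param n_false false detections implanted before April 1
#' @param n_slivers sub-1-ha artifact polygons appended as cleaning targets
#' @return list: \code{hotspots} (x, y, lon, acq_datetime, sensor, fire_id,
#'   ecozone; includes the false detections), \code{reference}
#'   (\code{perimeter_set} for fires with \code{has_reference}),
#'   \code{truth_perimeters} (\code{perimeter_set} of all true burned areas),
#'   \code{slivers} (\code{perimeter_set} of artifacts), \code{water}
#'   (circles: fire_id, cx, cy, r), \code{records}
#'   (\code{\link{fire_records}} table), \code{truth} (per-fire areas, truth
#'   day-of-burn grids, daily areas, false-detection and artifact ids)
#' @export
gen_fires <- function(fires, seed, res = 180, ha_per_hotspot = 25,
                      aspect = 0.65, n_false = 10, n_slivers = 3) {
  set.seed(seed)
  hot <- list(); ref_fires <- list(); truth_fires <- list()
  water <- list(); day_grids <- list(); areas <- list()
  for (k in seq_len(nrow(fires))) {
    f <- fires[k, ]
    one <- .gen_one_fire(f, res, aspect, ha_per_hotspot)
    hot[[k]] <- one$hotspots
    if (nrow(one$water)) water[[length(water) + 1]] <- one$water
    truth_fires[[k]] <- list(fire_id = f$id, frame = one$frame,
                             ids = one$ids, source = "truth",
                             ecozone = f$ecozone)
    if (isTRUE(f$has_reference))
      ref_fires[[length(ref_fires) + 1]] <- list(
        fire_id = f$id, frame = one$frame, ids = one$ids,
        source = "reference", ecozone = f$ecozone)
    day_grids[[k]] <- structure(list(
      frame = one$frame, ids = one$ids, day = one$day,
      origin = as.Date("1970-01-01"), fire_id = f$id,
      method = "truth", variogram = NULL), class = "burn_date_grid")
    tab <- table(one$day)
    areas[[k]] <- data.frame(fire_id = f$id,
                             date = as.Date(as.integer(names(tab)),
                                            origin = "1970-01-01"),
                             area_ha = as.numeric(tab) * res^2 / 1e4)
  }
  hotspots <- do.call(rbind, hot)
  # false detections before April 1, scattered around fire centroids
  yr <- as.integer(format(min(fires$ignition), "%Y"))
  false_ids <- character(0)
  if (n_false > 0) {
    pick <- sample.int(nrow(fires), n_false, replace = TRUE)
    fd <- data.frame(
      x = fires$cx[pick] + stats::runif(n_false, -5e3, 5e3),
      y = fires$cy[pick] + stats::runif(n_false, -5e3, 5e3),
      lon = fires$lon[pick],
      acq_datetime = as.POSIXct(sprintf("%d-03-%02d 20:00:00", yr,
                                        sample(1:25, n_false, TRUE)),
                                tz = "UTC"),
      sensor = "VIIRS-375",
      fire_id = paste0("false_", seq_len(n_false)),
      ecozone = fires$ecozone[pick])
    false_ids <- fd$fire_id
    hotspots <- rbind(hotspots, fd)
  }
  # sub-1-ha sliver artifacts on their own fine frames
  slivers <- list()
  for (s in seq_len(n_slivers)) {
    fr <- pixel_frame(stats::runif(1, 0, 1e5), stats::runif(1, 0, 1e5),
                      10, 10, 30)
    ctr <- frame_coords(fr, frame_index(fr, fr$xmin + 135, fr$ymin + 135))
    m <- .rasterize_discs(fr, ctr$x, ctr$y, 40)   # ~0.5 ha disc
    slivers[[s]] <- list(fire_id = paste0("sliver_", s), frame = fr,
                         ids = which(m), source = "buffered",
                         ecozone = fires$ecozone[1])
  }
  records <- data.frame(
    id = fires$id, size_ha = vapply(truth_fires, .fire_area_ha, 0),
    start = fires$ignition, out = fires$ignition + fires$n_days - 1,
    cause = sample(c("lightning", "human", "unknown"), nrow(fires), TRUE,
                   prob = c(0.6, 0.33, 0.07)),
    response = sample(c("full", "modified", "monitored"), nrow(fires), TRUE,
                      prob = c(0.79, 0.15, 0.06)),
    region = fires$ecozone, lon = fires$lon)
  truth <- list(
    per_fire = data.frame(id = fires$id, ecozone = fires$ecozone,
                          has_reference = fires$has_reference,
                          area_ha = vapply(truth_fires, .fire_area_ha, 0)),
    total_area_ha = sum(vapply(truth_fires, .fire_area_ha, 0)),
    day_grids = day_grids,
    daily_areas = do.call(rbind, areas),
    false_detection_ids = false_ids,
    artifact_ids = vapply(slivers, function(s) s$fire_id, ""))
  list(hotspots = hotspots,
       reference = .perimeter_set(ref_fires),
       truth_perimeters = .perimeter_set(truth_fires),
       slivers = .perimeter_set(slivers),
       water = if (length(water)) do.call(rbind, water) else
         data.frame(fire_id = character(), cx = numeric(), cy = numeric(),
                    r = numeric()),
       records = fire_records(records), truth = truth)
}

# One fire: ellipse day-of-burn field, lakes/islands, hotspot sampling.
.gen_one_fire <- function(f, res, aspect, ha_per_hotspot) {
  a_final <- sqrt(f$size_ha * 1e4 / (pi * aspect))
  incr <- abs(stats::rnorm(f$n_days, 1, 0.25))
  a_d <- a_final * cumsum(incr) / sum(incr)
  theta <- stats::runif(1, 0, pi)
  frame <- frame_around(f$cx, f$cy, margin = a_final + 4 * res, res = res)
  ids_all <- seq_len(frame$nx * frame$ny)
  xy <- frame_coords(frame, ids_all)
  u <- cos(theta) * (xy$x - f$cx) + sin(theta) * (xy$y - f$cy)
  v <- -sin(theta) * (xy$x - f$cx) + cos(theta) * (xy$y - f$cy)
  re <- sqrt(u^2 + (v / aspect)^2)     # burns when a_d reaches re
  # first day with a_d >= re (n_days + 1 means never burned)
  day_idx <- findInterval(re, a_d, left.open = TRUE) + 1L
  burned <- re <= a_final
  # water bodies and unburned islands carved from the true burned area
  carve <- function(n, rmin, rmax) {
    if (n < 1) return(data.frame(cx = numeric(), cy = numeric(), r = numeric()))
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- stats::runif(n, 0, 0.45 * a_final)
    data.frame(cx = f$cx + rad * cos(ang), cy = f$cy + rad * sin(ang),
               r = stats::runif(n, rmin, rmax))
  }
  lakes <- carve(f$n_lakes, 0.08 * a_final, 0.15 * a_final)
  islands <- carve(f$n_islands, 0.05 * a_final, 0.10 * a_final)
  if (nrow(lakes)) {
    wmask <- .rasterize_discs(frame, lakes$cx, lakes$cy, lakes$r)
    burned <- burned & !as.vector(wmask)[ids_all]
  }
  if (nrow(islands)) {
    imask <- .rasterize_discs(frame, islands$cx, islands$cy, islands$r)
    burned <- burned & !as.vector(imask)[ids_all]
  }
  ids <- ids_all[burned]
  day_rel <- day_idx[burned]
  day <- as.integer(as.numeric(f$ignition) + day_rel - 1)
  # hotspot sampling from each day's newly burned pixels
  off_s <- round(f$lon / 15) * 3600
  hs <- list()
  for (d in seq_len(f$n_days)) {
    new_ids <- ids[day_rel == d]
    if (!length(new_ids)) next
    n_h <- max(1L, round(length(new_ids) * res^2 / 1e4 / ha_per_hotspot))
    pick <- if (n_h >= length(new_ids)) new_ids else
      new_ids[sample.int(length(new_ids), n_h)]
    pxy <- frame_coords(frame, pick)
    n_p <- length(pick)
    local <- as.POSIXct((as.numeric(f$ignition) + d - 1) * 86400,
                        origin = "1970-01-01", tz = "UTC") +
      13 * 3600 + stats::runif(n_p, -7200, 7200)
    hs[[d]] <- data.frame(
      x = pxy$x + stats::runif(n_p, -res / 2, res / 2),
      y = pxy$y + stats::runif(n_p, -res / 2, res / 2),
      lon = f$lon,
      acq_datetime = local - off_s,
      sensor = "VIIRS-375", fire_id = f$id, ecozone = f$ecozone)
  }
  list(frame = frame, ids = ids, day = day,
       hotspots = do.call(rbind, hs),
       water = if (nrow(lakes))
         cbind(fire_id = f$id, lakes) else
         data.frame(fire_id = character(), cx = numeric(), cy = numeric(),
                    r = numeric()))
}

#' Reference national fire scenario (historical + evaluation year)
#'
#' Builds the package's standard burned-area recovery scenario: several
#' historical years of fires with both hotspots and reference perimeters
#' (used to optimize buffer radii and fit ecozone calibration factors), and
#' an evaluation year in which a stated share of fires has reference
#' perimeters and the rest are hotspot-only, plus false pre-season
#' detections and sliver artifacts.
#'
#' @param seed integer seed
#' @param n_eval evaluation-year fires (default 20)
#' @param n_zones ecozones (default 3)
#' @param n_hist_years historical years per zone (default 2)
#' @param n_hist_per_year historical fires per zone-year (default 2)
#' @param ref_share share of evaluation fires with reference perimeters
#' @param res pixel size (m)
#' @param ha_per_hotspot hotspot sampling density
#' @return list with \code{historic} and \code{eval} (each a
#'   \code{\link{gen_fires}} result), \code{hist_years}, \code{zones}
#' @export
gen_fire_scenario <- function(seed, n_eval = 20, n_zones = 3,
                              n_hist_years = 2, n_hist_per_year = 2,
                              ref_share = 0.6, res = 180,
                              ha_per_hotspot = 25) {
  set.seed(seed)
  zones <- paste0("zone", seq_len(n_zones))
  mk_positions <- function(n) {
    # well-separated centres on a coarse lattice with jitter
    i <- seq_len(n) - 1
    data.frame(cx = (i %% 5) * 6e4 + stats::runif(n, 0, 1e4),
               cy = (i %/% 5) * 6e4 + stats::runif(n, 0, 1e4))
  }
  n_hist <- n_zones * n_hist_years * n_hist_per_year
  hp <- mk_positions(n_hist)
  hist_years <- 2020 + seq_len(n_hist_years) - 1
  hist_tab <- data.frame(
    id = paste0("h", seq_len(n_hist)),
    cx = hp$cx, cy = hp$cy + 1e6,
    lon = stats::runif(n_hist, -125, -65),
    year = rep(hist_years, each = n_zones * n_hist_per_year),
    ecozone = rep(rep(zones, each = n_hist_per_year), times = n_hist_years),
    size_ha = exp(stats::runif(n_hist, log(800), log(3000))),
    n_days = sample(8:15, n_hist, TRUE),
    has_reference = TRUE,
    n_lakes = sample(0:2, n_hist, TRUE), n_islands = sample(0:2, n_hist, TRUE))
  hist_tab$ignition <- as.Date(sprintf("%d-06-01", hist_tab$year)) +
    sample(0:40, n_hist, TRUE)
  ep <- mk_positions(n_eval)
  eval_tab <- data.frame(
    id = paste0("f", seq_len(n_eval)),
    cx = ep$cx, cy = ep$cy,
    lon = stats::runif(n_eval, -125, -65),
    year = 2023,
    ecozone = sample(zones, n_eval, TRUE),
    size_ha = pmin(pmax(stats::rlnorm(n_eval, log(3000), 0.8), 700), 30000),
    n_days = sample(10:25, n_eval, TRUE),
    has_reference = seq_len(n_eval) <= round(ref_share * n_eval),
    n_lakes = sample(0:2, n_eval, TRUE), n_islands = sample(0:2, n_eval, TRUE))
  eval_tab$ignition <- as.Date("2023-05-15") + sample(0:60, n_eval, TRUE)
  historic <- gen_fires(hist_tab, seed = seed + 1, res = res,
                        ha_per_hotspot = ha_per_hotspot, n_false = 0,
                        n_slivers = 0)
  eval <- gen_fires(eval_tab, seed = seed + 2, res = res,
                    ha_per_hotspot = ha_per_hotspot, n_false = 12,
                    n_slivers = 3)
  list(historic = historic, eval = eval, hist_years = hist_years,
       zones = zones)
}
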