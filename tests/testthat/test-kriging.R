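# Hotspot preparation and day-of-burn interpolation.

test_that("hotspot preparation corrects to local standard time and filters", {
  hs <- data.frame(
    lon = c(-120, -120, -75),
    acq_datetime = as.POSIXct(c("2023-03-20 20:00:00", "2023-06-10 20:00:00",
                                "2023-06-10 02:00:00"), tz = "UTC"))
  out <- prepare_hotspots(hs)
  # the March 20 detection is dropped by the April 1 filter
  expect_equal(nrow(out), 2)
  # UTC 20:00 at lon -120 is local 12:00 (-8 h)
  expect_equal(format(out$local_datetime[1], "%H:%M", tz = "UTC"), "12:00")
  # UTC 02:00 at lon -75 is local 21:00 the previous day (-5 h)
  expect_equal(as.character(out$local_date[2]), "2023-06-09")
  # an all-in-season list passes through unchanged
  hs2 <- hs[2:3, ]
  expect_equal(nrow(prepare_hotspots(hs2)), 2)
})

mk_fire <- function(ids, frame) list(fire_id = "t", frame = frame, ids = ids)

test_that("single-day fires interpolate to a constant grid", {
  fr <- pixel_frame(0, 0, 30, 30, 60)
  ids <- which(brute_disc_mask(fr, 900, 900, 700))
  set.seed(2)
  pts <- data.frame(x = runif(40, 300, 1500), y = runif(40, 300, 1500),
                    local_date = as.Date("2023-06-10"))
  bg <- krige_burn_dates(pts, mk_fire(ids, fr))
  expect_true(all(bg$day == as.integer(as.Date("2023-06-10"))))
})

test_that("zero-nugget kriging honours the data at hotspot pixels", {
  fr <- pixel_frame(0, 0, 25, 25, 100)
  ids <- seq_len(25 * 25)
  set.seed(3)
  pick <- sample(ids, 30)
  xy <- fireseason:::frame_coords(fr, pick)
  dates <- as.Date("2023-07-01") + sample(0:9, 30, TRUE)
  pts <- data.frame(x = xy$x, y = xy$y, local_date = dates)
  bg <- krige_burn_dates(pts, mk_fire(ids, fr),
                         kriging_config(nugget = 0, sill = 9, range = 800))
  expect_equal(bg$day[match(pick, ids)], as.integer(dates))
})

test_that("fewer than five hotspots falls back to nearest neighbour", {
  fr <- pixel_frame(0, 0, 10, 10, 100)
  pts <- data.frame(x = c(150, 820), y = c(150, 820),
                    local_date = as.Date("2023-07-01") + c(0, 5))
  expect_warning(bg <- krige_burn_dates(pts, mk_fire(seq_len(100), fr)),
                 "nearest")
  expect_equal(bg$method, "nearest")
  # corner pixels take the date of the closest hotspot
  expect_equal(bg$day[1], as.integer(pts$local_date[1]))
  expect_equal(bg$day[100], as.integer(pts$local_date[2]))
})

test_that("daily series conserve footprint area and respect regions", {
  fires <- data.frame(id = c("a", "b"), cx = c(0, 50000), cy = 0,
                      lon = c(-115, -70),
                      ignition = as.Date("2023-06-01") + c(0, 10),
                      n_days = c(8, 12), size_ha = c(900, 1500),
                      ecozone = c("z1", "z2"), has_reference = TRUE,
                      n_lakes = 0, n_islands = 0)
  gf <- gen_fires(fires, seed = 4, res = 120, ha_per_hotspot = 20,
                  n_false = 0, n_slivers = 0)
  das <- daily_area_series(gf$truth$day_grids,
                           regions = c(a = "west", b = "east"))
  per <- attr(das, "per_fire")
  for (i in 1:2) {
    fid <- fires$id[i]
    expect_equal(sum(per$area_ha[per$fire_id == fid]),
                 length(gf$truth$day_grids[[i]]$ids) * 120^2 / 1e4)
  }
  expect_setequal(unique(das$region), c("west", "east"))
  # a single-day fire puts all area on that day
  fr <- pixel_frame(0, 0, 10, 10, 100)
  g1 <- structure(list(frame = fr, ids = 1:60,
                       day = rep(19000L, 60), origin = as.Date("1970-01-01"),
                       fire_id = "s", method = "truth"),
                  class = "burn_date_grid")
  d1 <- daily_area_series(list(g1))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$area_ha, 60)
  # overlapping grids on the same frame are rejected
  g2 <- structure(list(frame = fr, ids = 50:80, day = rep(19001L, 31),
                       origin = as.Date("1970-01-01"), fire_id = "s2",
                       method = "truth"), class = "burn_date_grid")
  expect_error(daily_area_series(list(g1, g2)), "overlap")
})

test_that("interpolated dates grow outward on a radially growing fire", {
  fires <- data.frame(id = "r", cx = 0, cy = 0, lon = -100,
                      ignition = as.Date("2023-06-01"), n_days = 15,
                      size_ha = 4000, ecozone = "z", has_reference = TRUE,
                      n_lakes = 0, n_islands = 0)
  gf <- gen_fires(fires, seed = 13, res = 120, ha_per_hotspot = 15,
                  n_false = 0, n_slivers = 0)
  hs <- prepare_hotspots(gf$hotspots)
  bg <- krige_burn_dates(hs, gf$reference$fires[[1]])
  truth <- gf$truth$day_grids[[1]]
  expect_lte(mean(abs(bg$day - truth$day)), 1.5)
  xy <- fireseason:::frame_coords(bg$frame, bg$ids)
  r <- sqrt(xy$x^2 + xy$y^2)
  bins <- cut(r, quantile(r, seq(0, 1, 0.25)), include.lowest = TRUE)
  mean_day <- tapply(bg$day, bins, mean)
  expect_true(all(diff(mean_day) > 0))
})
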