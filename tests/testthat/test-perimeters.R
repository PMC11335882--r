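# Hotspot buffering, radius optimization, calibration, cleaning, hybrid
# merge and land-cover intersection.

test_that("an isolated hotspot becomes a disc of radius r_out - r_in", {
  h <- data.frame(x = 5000, y = 5000)
  ps <- buffer_hotspots(h, buffer_params(500, 200), res = 5)
  area <- as.data.frame(ps)$area_ha
  expect_equal(area, pi * 300^2 / 1e4, tolerance = 0.005)
  # with no contraction the buffer identity holds at r_out
  ps0 <- buffer_hotspots(h, buffer_params(500, 0), res = 5)
  expect_equal(as.data.frame(ps0)$area_ha, pi * 500^2 / 1e4,
               tolerance = 0.005)
})

test_that("dissolving joins close hotspots and keeps distant ones apart", {
  near <- data.frame(x = c(0, 900), y = c(0, 0))
  ps <- buffer_hotspots(near, buffer_params(500, 0), res = 10)
  m <- matrix(FALSE, ps$fires[[1]]$frame$ny, ps$fires[[1]]$frame$nx)
  m[ps$fires[[1]]$ids] <- TRUE
  expect_equal(max(fireseason:::.label_mask(m)), 1)   # one dissolved polygon
  far <- data.frame(x = c(0, 10000), y = c(0, 0))
  ps2 <- buffer_hotspots(far, buffer_params(500, 0), res = 10)
  m2 <- matrix(FALSE, ps2$fires[[1]]$frame$ny, ps2$fires[[1]]$frame$nx)
  m2[ps2$fires[[1]]$ids] <- TRUE
  expect_equal(max(fireseason:::.label_mask(m2)), 2)  # two separate polygons
})

test_that("contraction is monotone and parameters are validated", {
  set.seed(2)
  h <- data.frame(x = runif(30, 0, 3000), y = runif(30, 0, 3000))
  areas <- sapply(c(0, 100, 200, 300), function(rin)
    sum(as.data.frame(buffer_hotspots(h, buffer_params(400, rin),
                                      res = 20))$area_ha))
  expect_true(all(diff(areas) <= 0))
  expect_error(buffer_params(300, 300), "r_out > r_in")
  expect_error(buffer_params(300, -5), "r_out > r_in")
  expect_length(buffer_hotspots(data.frame(x = numeric(), y = numeric()),
                                buffer_params(500, 0))$fires, 0)
})

test_that("radius optimization maximizes IoU with deterministic tie-breaks", {
  # reference = disc of radius 400 around a central hotspot: the candidate
  # equal to the disc radius must win, scored by an independent brute pixel
  # comparison
  set.seed(6)
  fr <- pixel_frame(-1000, -1000, 101, 101, 20)
  ref_mask <- brute_disc_mask(fr, 0, 0, 400)
  ref <- structure(list(fires = list(list(fire_id = "r1", frame = fr,
                                          ids = which(ref_mask),
                                          source = "reference",
                                          ecozone = "zA"))),
                   class = "perimeter_set")
  hs <- data.frame(x = 0, y = 0, fire_id = "r1")
  cand <- expand.grid(r_out = c(100, 200, 400, 700), r_in = 0)
  opt <- optimize_radii(hs, ref, cand)
  expect_equal(opt$r_out, 400)
  # the winner's IoU beats every other candidate under the brute scorer,
  # also for dense multi-hotspot input
  ang <- runif(200, 0, 2 * pi); rad <- sqrt(runif(200)) * 380
  hs_dense <- data.frame(x = rad * cos(ang), y = rad * sin(ang),
                         fire_id = "r1")
  opt_d <- optimize_radii(hs_dense, ref, cand)
  brute_iou <- function(r_out) {
    buf <- brute_disc_mask(fr, hs_dense$x, hs_dense$y, r_out)
    sum(buf & ref_mask) / sum(buf | ref_mask)
  }
  for (r in cand$r_out) expect_gte(opt_d$iou + 1e-9, brute_iou(r))
  # candidate set of size 1 is returned as-is
  one <- optimize_radii(hs, ref, data.frame(r_out = 250, r_in = 50))
  expect_equal(c(one$r_out, one$r_in), c(250, 50))
  # tiny reference polygons pull the optimum to the smallest radii
  tiny_ids <- which(brute_disc_mask(fr, 0, 0, 30))
  ref2 <- structure(list(fires = list(list(fire_id = "r1", frame = fr,
                                           ids = tiny_ids,
                                           source = "reference",
                                           ecozone = "zA"))),
                    class = "perimeter_set")
  hs2 <- data.frame(x = 0, y = 0, fire_id = "r1")
  opt2 <- optimize_radii(hs2, ref2, cand)
  expect_equal(opt2$r_out, 100)
})

test_that("calibration factors are the mean of yearly reference/buffered ratios", {
  a <- data.frame(ecozone = "z1", year = 2012:2016,
                  ref_area_ha = 80, buf_area_ha = 100)
  expect_equal(calibration_factors(a)$factor, 0.8)
  b <- data.frame(ecozone = "z1", year = 2012:2013,
                  ref_area_ha = c(60, 100), buf_area_ha = c(100, 100))
  expect_equal(calibration_factors(b)$factor, 0.8)
  set.seed(3)
  r <- data.frame(ecozone = rep(c("a", "b"), each = 6),
                  year = rep(2012:2017, 2),
                  ref_area_ha = runif(12, 50, 150),
                  buf_area_ha = runif(12, 80, 160))
  got <- calibration_factors(r)
  for (z in c("a", "b")) {
    rz <- r[r$ecozone == z, ]
    expect_equal(got$factor[got$ecozone == z],
                 mean(rz$ref_area_ha / rz$buf_area_ha))
  }
  # pooled aggregation and zero-buffered strata
  expect_equal(calibration_factors(b, method = "pooled")$factor, 160 / 200)
  bz <- rbind(b, data.frame(ecozone = "z1", year = 2014, ref_area_ha = 10,
                            buf_area_ha = 0))
  expect_warning(f <- calibration_factors(bz), "zero buffered")
  expect_equal(f$factor, 0.8)
})

test_that("cleaning removes sub-1-ha polygons and erases water", {
  fr <- pixel_frame(0, 0, 60, 60, 30)
  small <- which(brute_disc_mask(fr, 900, 900, 40))        # ~0.5 ha
  big <- which(brute_disc_mask(fr, 300, 300, 250))         # ~19 ha
  ps <- structure(list(fires = list(
    list(fire_id = "s", frame = fr, ids = small, source = "buffered",
         ecozone = "z"),
    list(fire_id = "b", frame = fr, ids = big, source = "buffered",
         ecozone = "z"))), class = "perimeter_set")
  cl <- clean_polygons(ps)
  expect_equal(as.data.frame(cl)$fire_id, "b")             # 0.5 ha removed
  # a lake inside the big polygon removes exactly its pixels
  lake <- data.frame(fire_id = "b", cx = 300, cy = 300, r = 100)
  cl2 <- clean_polygons(ps, water = lake)
  lake_px <- which(brute_disc_mask(fr, 300, 300, 100))
  expect_equal(length(cl2$fires[[1]]$ids), length(setdiff(big, lake_px)))
  # no overlap with water leaves the polygon unchanged
  cl3 <- clean_polygons(ps, water = data.frame(fire_id = "x", cx = 1e6,
                                               cy = 1e6, r = 100))
  expect_setequal(cl3$fires[[1]]$ids, big)
})

test_that("hybrid merge is additive and rejects duplicated fires", {
  fr <- pixel_frame(0, 0, 100, 100, 100)       # 1 px = 1 ha
  mk <- function(id, n, source, zone) list(fire_id = id, frame = fr,
                                           ids = seq_len(n), source = source,
                                           ecozone = zone)
  ref <- structure(list(fires = list(mk("a", 100000 %/% 10, "reference", "z1"))),
                   class = "perimeter_set")   # 10,000 ha
  buf <- structure(list(fires = list(mk("b", 5000, "buffered", "z1"))),
                   class = "perimeter_set")   # 5,000 ha
  fac <- data.frame(ecozone = "z1", factor = 0.8, n_years = 5)
  hy <- merge_hybrid(ref, buf, fac)
  expect_equal(hy$total_ha, 10000 + 5000 * 0.8)
  # empty buffered set reduces to the reference total
  hy0 <- merge_hybrid(ref, structure(list(fires = list()),
                                     class = "perimeter_set"), fac)
  expect_equal(hy0$total_ha, 10000)
  expect_equal(hy$total_ha, sum(hy$table$calibrated_ha))   # additivity
  dup <- structure(list(fires = list(mk("a", 10, "buffered", "z1"))),
                   class = "perimeter_set")
  expect_error(merge_hybrid(ref, dup, fac), "both sources")
})

test_that("land-cover proportions tally burned pixels by class", {
  lc_frame <- pixel_frame(0, 0, 40, 40, 100)
  classes <- matrix(7L, 40, 40)        # uniform Treed conifer
  names7 <- c("Water", "Rock", "Bryoid", "Herbs", "Shrub", "Treed broadleaf",
              "Treed conifer", "Treed mixed")
  lc <- list(frame = lc_frame, classes = classes, class_names = names7)
  fr <- pixel_frame(500, 500, 20, 20, 100)
  fire <- list(fire_id = "f", frame = fr, ids = 1:400, source = "hybrid",
               ecozone = "z")
  ps <- structure(list(fires = list(fire)), class = "perimeter_set")
  p <- landcover_proportions(ps, lc)
  expect_equal(p$proportions[["Treed conifer"]], 1)
  # half conifer / half broadleaf split exactly along the polygon midline
  classes2 <- classes
  classes2[, 1:15] <- 6L   # x <= 1450 -> broadleaf; fire spans x 500..2400
  lc2 <- list(frame = lc_frame, classes = classes2, class_names = names7)
  p2 <- landcover_proportions(ps, lc2)
  expect_equal(p2$proportions[["Treed broadleaf"]], 0.5, tolerance = 1e-9)
  expect_equal(rowSums(p2$proportions), c(all = 1))
  # random mosaic against a brute per-pixel tally
  set.seed(12)
  classes3 <- matrix(sample(1:8, 1600, TRUE), 40, 40)
  lc3 <- list(frame = lc_frame, classes = classes3, class_names = names7)
  p3 <- landcover_proportions(ps, lc3)
  xy <- fireseason:::frame_coords(fr, fire$ids)
  idx <- fireseason:::frame_index(lc_frame, xy$x, xy$y)
  tallies <- table(factor(names7[classes3[idx]],
                          levels = setdiff(names7, c("Water", "Rock"))))
  expect_equal(unname(unlist(p3$proportions[1, ])),
               as.numeric(tallies[colnames(p3$proportions)] / sum(tallies)))
  # polygons outside the raster are an error naming the fire
  far_fire <- list(fire_id = "far", frame = pixel_frame(1e6, 1e6, 5, 5, 100),
                   ids = 1:25, source = "hybrid", ecozone = "z")
  ps_far <- structure(list(fires = list(far_fire)), class = "perimeter_set")
  expect_error(landcover_proportions(ps_far, lc), "far")
})
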