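# Persistent positive anomaly detection: standardization, event criteria
# (threshold, persistence, area), linkage, day counting, monotone filtering.

test_that("height anomalies standardize against the monthly climatology", {
  set.seed(14)
  dates <- seq(as.Date("2000-01-01"), as.Date("2004-12-31"), by = 1)
  n <- length(dates)
  h <- matrix(rnorm(6 * n, 5500, 40), 6, n)
  z <- anomaly_field(h, dates, 2000:2003)
  mon <- as.integer(format(dates, "%m"))
  yrs <- as.integer(format(dates, "%Y"))
  # brute-force per-cell per-month mean/sd over the baseline
  for (cell in c(1, 4)) for (m in c(2, 7)) {
    base <- h[cell, yrs %in% 2000:2003 & mon == m]
    cols <- which(mon == m)
    expect_equal(z[cell, cols], (h[cell, cols] - mean(base)) / sd(base))
  }
  # heights equal to climatology give z = 0; a +2 sd bump gives z = 2
  h2 <- h
  julcols <- which(mon == 7 & yrs == 2004)
  base <- h[2, yrs %in% 2000:2003 & mon == 7]
  h2[2, julcols] <- mean(base)
  h2[2, julcols[1:5]] <- mean(base) + 2 * sd(base)
  z2 <- anomaly_field(h2, dates, 2000:2003)
  expect_equal(unname(z2[2, julcols[6:10]]), rep(0, 5))
  expect_equal(unname(z2[2, julcols[1:5]]), rep(2, 5))
})

# a clean z field with implants is enough to exercise detect_events
implant_z <- function(g, ndays, blocks) {
  z <- matrix(0, g$ncell, ndays)
  for (b in blocks) z[b$cells, b$days] <- b$amp
  z
}

test_that("events require threshold, persistence and area simultaneously", {
  g <- ws_grid(seq(-130, -106, 1), seq(48, 62, 1))
  dates <- seq(as.Date("2010-06-01"), by = 1, length.out = 40)
  big <- as.vector(outer(3:8, (3:7 - 1) * g$nlon, "+"))  # 30 cells, ~230k km2
  z <- implant_z(g, 40, list(list(cells = big, days = 5:11, amp = 2)))
  ev <- detect_events(z, dates, g, blocking_config())
  expect_length(ev, 1)
  expect_equal(ev[[1]]$duration, 7)
  expect_equal(ev[[1]]$start, dates[5])
  expect_gte(ev[[1]]$max_area_km2, 1e5)
  expect_setequal(ev[[1]]$cells[[1]], big)
  # same ridge lasting 4 days fails persistence
  z4 <- implant_z(g, 40, list(list(cells = big, days = 5:8, amp = 2)))
  expect_length(detect_events(z4, dates, g, blocking_config()), 0)
  # small footprint fails the area criterion even with long persistence
  tiny <- as.vector(outer(3:4, (3:4 - 1) * g$nlon, "+"))  # 4 cells
  zt <- implant_z(g, 40, list(list(cells = tiny, days = 5:20, amp = 2)))
  expect_length(detect_events(zt, dates, g, blocking_config()), 0)
})

test_that("two disjoint simultaneous ridges give two events", {
  g <- ws_grid(seq(-130, -106, 1), seq(48, 62, 1))
  dates <- seq(as.Date("2010-06-01"), by = 1, length.out = 20)
  a <- as.vector(outer(2:7, (2:6 - 1) * g$nlon, "+"))
  b <- as.vector(outer(15:20, (9:13 - 1) * g$nlon, "+"))
  z <- implant_z(g, 20, list(list(cells = a, days = 3:9, amp = 2),
                             list(cells = b, days = 3:9, amp = 2)))
  ev <- detect_events(z, dates, g, blocking_config())
  expect_length(ev, 2)
})

test_that("implanted scenario is recovered exactly, including day counts", {
  bs <- gen_blocking_scenario(seed = 42)
  z <- anomaly_field(bs$heights, bs$dates, bs$truth$baseline_years)
  yr <- as.integer(format(bs$dates, "%Y")) == bs$truth$eval_year
  ev <- detect_events(z[, yr], bs$dates[yr], bs$grid, bs$config)
  truth_q <- bs$truth$implants[bs$truth$implants$qualifies, ]
  expect_equal(length(ev), nrow(truth_q))     # recall and precision both 1
  dm <- blocking_day_map(ev, bs$grid, bs$dates[yr])
  expect_identical(dm, bs$truth$day_count)
  # flagged (cell, day) pairs are partitioned: summing per-event membership
  # never double-counts
  tot_cells <- sum(vapply(ev, function(e) sum(lengths(e$cells)), 0))
  expect_equal(sum(dm), tot_cells)
})

test_that("raising thresholds never increases the number of events", {
  bs <- gen_blocking_scenario(seed = 8)
  z <- anomaly_field(bs$heights, bs$dates, bs$truth$baseline_years)
  yr <- as.integer(format(bs$dates, "%Y")) == bs$truth$eval_year
  zz <- z[, yr]; dts <- bs$dates[yr]
  n_base <- length(detect_events(zz, dts, bs$grid, blocking_config()))
  n_hi <- length(detect_events(zz, dts, bs$grid,
                               blocking_config(sd_threshold = 2)))
  n_long <- length(detect_events(zz, dts, bs$grid,
                                 blocking_config(min_days = 8)))
  expect_lte(n_hi, n_base)
  expect_lte(n_long, n_base)
  # relabeling days outside April-October leaves detection unchanged
  zz2 <- zz
  mon <- as.integer(format(dts, "%m"))
  zz2[, mon %in% c(1:3, 11:12)] <- 99
  ev1 <- detect_events(zz, dts, bs$grid, blocking_config())
  ev2 <- detect_events(zz2, dts, bs$grid, blocking_config())
  expect_equal(lapply(ev1, `[[`, "days"), lapply(ev2, `[[`, "days"))
})
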