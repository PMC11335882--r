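# Extreme-fire-weather climatology: VPD, percentile fields, extent series,
# extreme-day counts, standardized anomalies, seasonal ranks, and the
# extent-vs-burn rank correlation.

# minimal fwi_fields stand-in: explicit index values and season mask
fake_fields <- function(values, active, dates, grid = NULL) {
  if (is.null(grid))
    grid <- ws_grid(seq(-110, by = 0.5, length.out = 1), 55)
  list(fwi = values, active = active, dates = dates, grid = grid)
}

test_that("VPD is zero at saturation, clamps supersaturation, matches Magnus", {
  expect_equal(vpd_from_t_td(18, 18), 0)
  expect_warning(v <- vpd_from_t_td(10, 12), "clamped")
  expect_equal(v, 0)
  expect_equal(vpd_from_t_td(30, 10), brute_vpd(30, 10))
  set.seed(3)
  t <- runif(50, -10, 35); td <- t - runif(50, 0, 15)
  expect_equal(vpd_from_t_td(t, td), brute_vpd(t, td))
  expect_true(all(vpd_from_t_td(t, td) >= 0))
})

test_that("percentile field: constants, brute-force quantile, off-season immunity", {
  dates <- seq(as.Date("2000-05-01"), by = 1, length.out = 200)
  vals <- matrix(7, 2, 200)
  act <- matrix(TRUE, 2, 200)
  ff <- fake_fields(vals, act, dates,
                    ws_grid(seq(-110, by = 0.5, length.out = 2), 55))
  pf <- percentile_field(ff, 2000, min_days = 10)
  expect_equal(pf$q95, c(7, 7))
  # in-season values 1..100 at cell 1, rest off-season
  vals[1, ] <- c(1:100, rep(9999, 100))
  act[1, ] <- c(rep(TRUE, 100), rep(FALSE, 100))
  ff <- fake_fields(vals, act, dates,
                    ws_grid(seq(-110, by = 0.5, length.out = 2), 55))
  pf <- percentile_field(ff, 2000, min_days = 10)
  expect_equal(pf$q95[1], brute_quantile7(1:100, 0.95))
  # modifying off-season values changes nothing
  vals2 <- vals; vals2[1, 101:200] <- -5
  pf2 <- percentile_field(fake_fields(vals2, act, dates, ff$grid), 2000,
                          min_days = 10)
  expect_identical(pf$q95, pf2$q95)
  # permutation of days leaves the percentile unchanged
  perm <- sample(200)
  pf3 <- percentile_field(fake_fields(vals[, perm, drop = FALSE],
                                      act[, perm, drop = FALSE],
                                      dates, ff$grid), 2000, min_days = 10)
  expect_equal(pf3$q95, pf$q95)
  # cells below the day floor are masked
  pf4 <- percentile_field(ff, 2000, min_days = 150)
  expect_true(is.na(pf4$q95[1]) && !is.na(pf4$q95[2]))
  expect_error(percentile_field(ff, 1990), "baseline")
})

test_that("extent series sums the right areas and proportions", {
  g <- ws_grid(seq(-110, by = 0.5, length.out = 2),
               seq(54, by = 0.5, length.out = 2))
  dates <- seq(as.Date("2001-06-01"), by = 1, length.out = 3)
  vals <- matrix(c(10, 10, 10, 10,
                   1, 1, 1, 1,
                   10, 1, 1, 1), 4, 3)
  act <- matrix(TRUE, 4, 3)
  ff <- fake_fields(vals, act, dates, g)
  pf <- structure(list(q95 = rep(5, 4), n_days = rep(99, 4),
                       baseline_years = 2001, q = 0.95, index = "fwi"),
                  class = "percentile_field")
  ex <- extent_series(ff, pf)
  expect_equal(ex$area_km2,
               c(sum(g$cell_area_km2), 0, g$cell_area_km2[1]))
  expect_equal(ex$proportion, c(1, 0, g$cell_area_km2[1] / sum(g$cell_area_km2)))
  expect_equal(ex$area_ha, ex$area_km2 * 100)
  # uniform rescaling of cell areas leaves proportions unchanged
  ex2 <- extent_series(ff, pf, cell_area_km2 = g$cell_area_km2 * 3.7)
  expect_equal(ex2$proportion, ex$proportion)
  expect_equal(ex2$proportion_active, ex$proportion_active)
  # misaligned grids rejected
  bad <- structure(list(q95 = rep(5, 3), index = "fwi"),
                   class = "percentile_field")
  expect_error(extent_series(ff, bad), "misaligned")
})

test_that("extreme-day counts and anomalies count strict exceedances", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2001-12-31"), by = 1)
  n <- length(dates)
  vals <- matrix(0, 2, n); act <- matrix(TRUE, 2, n)
  yr <- format(dates, "%Y")
  # cell 1: exactly 7 exceedances in 2001, 3 in baseline 2000
  vals[1, which(yr == "2001")[1:7]] <- 10
  vals[1, which(yr == "2000")[1:3]] <- 10
  ff <- fake_fields(vals, act, dates,
                    ws_grid(seq(-110, by = 0.5, length.out = 2), 55))
  pf <- structure(list(q95 = c(5, 5), baseline_years = 2000, q = 0.95,
                       index = "fwi"), class = "percentile_field")
  ec <- extreme_day_counts(ff, pf, 2001)
  expect_equal(ec$count, c(7, 0))
  expect_equal(ec$baseline_mean, c(3, 0))
  expect_equal(ec$anomaly, c(4, 0))
})

test_that("standardized anomalies are z-scores with masking at zero sd", {
  set.seed(11)
  base <- matrix(rnorm(50 * 8, 100, 12), 50, 8)
  mu <- rowMeans(base)
  sd <- apply(base, 1, sd)
  expect_equal(standardized_anomaly(mu, base), rep(0, 50))
  expect_equal(standardized_anomaly(mu + sd, base), rep(1, 50))
  x <- rnorm(50, 100, 12)
  expect_equal(standardized_anomaly(x, base), (x - mu) / sd)
  base[3, ] <- 42
  expect_warning(z <- standardized_anomaly(x, base), "zero")
  expect_true(is.na(z[3]))
})

test_that("seasonal anomalies and ranks match brute-force sorting", {
  set.seed(21)
  dates <- seq(as.Date("2000-01-01"), as.Date("2009-12-31"), by = 1)
  vals <- matrix(rnorm(4 * length(dates), 15, 4), 4, length(dates))
  r <- season_anomaly_rank(vals, dates, target_year = 2009,
                           baseline_years = 2000:2008,
                           eval_years = 2000:2009)
  mon <- as.integer(format(dates, "%m")); yrs <- as.integer(format(dates, "%Y"))
  for (cell in 1:4) {
    sm <- sapply(2000:2009, function(y)
      mean(vals[cell, yrs == y & mon %in% 5:10]))
    expect_equal(unname(r$anomaly[cell]), sm[10] - mean(sm[1:9]))
    expect_equal(unname(r$rank[cell]),
                 which(order(sm, decreasing = TRUE) == 10))
  }
  # direction = "low" ranks the driest year first
  rlow <- season_anomaly_rank(vals, dates, 2009, 2000:2008, 2000:2009,
                              direction = "low")
  expect_true(all(rlow$rank == 11 - r$rank))
  expect_error(season_anomaly_rank(vals, dates, 2012, 2000:2008, 2000:2009),
               "missing years")
})

test_that("extent-burn correlation is Spearman with midranks", {
  d <- seq(as.Date("2023-06-01"), by = 1, length.out = 10)
  ex <- data.frame(date = d, region = "A", area_ha = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  bu <- data.frame(date = d, region = "A", area_ha = ex$area_ha^3 + 2)
  expect_equal(correlate_extent_burn(ex, bu)$rho, 1)
  bu2 <- bu; bu2$area_ha <- -bu$area_ha
  expect_equal(correlate_extent_burn(ex, bu2)$rho, -1)
  # ties handled by midranks; compare against the explicit computation
  set.seed(9)
  ex$area_ha <- sample(1:4, 10, TRUE)
  bu$area_ha <- sample(1:3, 10, TRUE)
  expect_equal(correlate_extent_burn(ex, bu)$rho,
               brute_spearman(ex$area_ha, bu$area_ha))
  # monotone transform invariance
  ex2 <- ex; ex2$area_ha <- exp(ex$area_ha)
  expect_equal(correlate_extent_burn(ex2, bu)$rho,
               correlate_extent_burn(ex, bu)$rho)
  # fewer than 3 paired days is undefined
  expect_warning(r <- correlate_extent_burn(ex[1:2, ], bu[1:2, ]), "fewer")
  expect_true(is.na(r$rho))
})
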