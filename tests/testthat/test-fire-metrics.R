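# Fire-level summaries: size classes, ignition months, duration/spread-day
# analysis with the power-law size relation, cause/response tables, PM2.5.

mk_records <- function(sizes, months = NULL, cause = "lightning",
                       response = "full", lon = -110) {
  n <- length(sizes)
  if (is.null(months)) months <- rep(6, n)
  fire_records(data.frame(
    id = paste0("f", seq_len(n)), size_ha = sizes,
    start = as.Date(sprintf("2023-%02d-05", months)),
    out = as.Date(sprintf("2023-%02d-05", months)) + 10,
    cause = rep_len(cause, n), response = rep_len(response, n),
    region = "r", lon = rep_len(lon, n)))
}

test_that("size classes use strict exceedance and partition the records", {
  r <- mk_records(c(200, 150, 900, 60000, 120000))
  s <- size_summary(r)
  # a fire of exactly 200 ha is not 'large'
  expect_equal(s$count[s$class == "(0,200]"], 2L)
  expect_equal(s$count[s$class == "(200,1e+03]"], 1L)
  expect_equal(s$count[s$class == "(5e+04,1e+05]"], 1L)
  expect_equal(s$count[s$class == "(1e+05,Inf]"], 1L)
  expect_equal(sum(s$count), 5L)
  expect_equal(sum(s$count_prop), 1)
  expect_equal(sum(s$area_prop), 1)
  set.seed(2)
  r2 <- mk_records(exp(runif(60, log(10), log(2e5))))
  s2 <- size_summary(r2)
  expect_equal(sum(s2$count), 60L)
  expect_equal(s2$area_ha[1],
               sum(r2$size_ha[r2$size_ha <= 200]))
})

test_that("ignition-month proportions cover counts and area", {
  r <- mk_records(c(5000, 5000, 5000, 5000), months = c(5, 5, 5, 7))
  im <- ignition_month_summary(r)
  expect_equal(im$count_prop, c(0.75, 0.25))
  expect_equal(im$area_prop, c(0.75, 0.25))
  expect_equal(sum(im$count_prop), 1)
  # only fires above the floor are included
  r2 <- mk_records(c(500, 5000), months = c(5, 8))
  im2 <- ignition_month_summary(r2)
  expect_equal(im2$month, 8L)
  expect_equal(im2$count_prop, 1)
  set.seed(7)
  r3 <- mk_records(exp(runif(40, log(1100), log(9e4))),
                   months = sample(4:9, 40, TRUE))
  im3 <- ignition_month_summary(r3)
  m <- as.integer(format(r3$start, "%m"))
  for (k in seq_len(nrow(im3))) {
    expect_equal(im3$count_prop[k], mean(m == im3$month[k]))
    expect_equal(im3$area_prop[k],
                 sum(r3$size_ha[m == im3$month[k]]) / sum(r3$size_ha))
  }
})

test_that("spread days count extreme days over the fire's footprint cells", {
  g <- ws_grid(seq(-120, -96, 2), c(54, 56))
  dates <- seq(as.Date("2023-06-01"), by = 1, length.out = 30)
  vals <- matrix(0, g$ncell, 30)
  vals[1, c(3, 5, 7, 9)] <- 10          # 4 extreme days at cell 1
  vals[2, 4] <- 10
  ff <- list(fwi = vals, active = matrix(TRUE, g$ncell, 30), dates = dates,
             grid = g)
  pf <- structure(list(q95 = rep(5, g$ncell), index = "fwi",
                       baseline_years = 2022, q = 0.95),
                  class = "percentile_field")
  rec <- fire_records(data.frame(
    id = c("w", "e"), size_ha = c(1000, 2000),
    start = as.Date("2023-06-01"), out = as.Date("2023-06-10"),
    cause = "lightning", response = "full", region = "r",
    lon = c(-120, -70)))
  res <- duration_spread_analysis(rec, list(w = 1L, e = c(1L, 2L)), ff, pf)
  expect_equal(res$per_fire$spread_days, c(4L, 5L))
  expect_equal(res$per_fire$duration, c(10L, 10L))
  expect_equal(res$per_fire$side, c("west", "east"))
  expect_equal(res$by_side$median_duration, c(10, 10))
  expect_equal(res$by_side$lo90, res$by_side$hi90)   # degenerate interval
})

test_that("the power-law exponent is recovered within two standard errors", {
  g <- ws_grid(seq(-120, -96, 2), c(54, 56))
  nd <- 120
  dates <- seq(as.Date("2023-05-01"), by = 1, length.out = nd)
  set.seed(33)
  vals <- matrix(rexp(g$ncell * nd, 1 / 10), g$ncell, nd)
  ff <- list(fwi = vals, active = matrix(TRUE, g$ncell, nd), dates = dates,
             grid = g)
  pf <- structure(list(q95 = apply(vals, 1, quantile, 0.95), index = "fwi",
                       baseline_years = 2022, q = 0.95),
                  class = "percentile_field")
  # the 2-SE band is a ~95% event per draw, so require 4 of 6 replicate
  # scenarios inside it for each exponent
  for (gamma in c(0.5, 1, 2)) {
    hits <- 0
    for (rep in 1:6) {
      n <- 200
      starts <- sample(seq_len(nd - 40), n, TRUE)
      durs <- sample(10:35, n, TRUE)
      cells <- sample(g$ncell, n, TRUE)
      rec <- data.frame(id = paste0("p", 1:n), start = dates[starts],
                        out = dates[pmin(starts + durs, nd)],
                        cause = "lightning", response = "full", region = "r",
                        lon = runif(n, -120, -96))
      fire_cells <- as.list(cells); names(fire_cells) <- rec$id
      # spread days computed independently, then sizes generated from them
      exceed <- sweep(vals, 1, pf$q95, ">")
      sdays <- vapply(seq_len(n), function(i)
        sum(exceed[cells[i], which(dates >= rec$start[i] &
                                   dates <= rec$out[i])]), 0)
      rec$size_ha <- exp(log(50) + gamma * log(sdays + 1) + rnorm(n, 0, 0.4))
      res <- duration_spread_analysis(fire_records(rec), fire_cells, ff, pf)
      hits <- hits + (abs(res$power_law$gamma - gamma) <
                        2 * res$power_law$se)
    }
    expect_gte(hits, 4)
  }
})

test_that("cause/response tabulations and containment match hand counts", {
  r <- mk_records(c(100, 150, 180, 120, 900), cause = "lightning")
  rc <- response_cause_summary(r)
  expect_equal(rc$by_cause$count_prop[rc$by_cause$level == "lightning"], 1)
  # 4 of 5 full-response fires are held under 200 ha
  expect_equal(rc$containment$containment, 0.8)
  set.seed(5)
  r2 <- mk_records(exp(runif(50, log(10), log(5e4))),
                   cause = sample(c("lightning", "human"), 50, TRUE),
                   response = sample(c("full", "modified"), 50, TRUE))
  rc2 <- response_cause_summary(r2)
  expect_equal(sum(rc2$by_cause$count_prop), 1)
  expect_equal(sum(rc2$by_response$area_prop), 1)
  for (lv in rc2$by_cause$level)
    expect_equal(rc2$by_cause$area_ha[rc2$by_cause$level == lv],
                 sum(r2$size_ha[r2$cause == lv]))
  for (resp in rc2$containment$response) {
    sub <- r2[r2$response == resp, ]
    expect_equal(rc2$containment$containment[rc2$containment$response == resp],
                 mean(sub$size_ha < 200))
  }
})

test_that("PM2.5 exceedance counts strict threshold crossings", {
  x <- c(10, 30, 27, 50, 5, 28)
  r <- pm25_exceedance(x)
  expect_equal(r$exceedance_days, 3L)
  expect_equal(r$annual_max, 50)
  expect_equal(pm25_exceedance(rep(27, 100))$exceedance_days, 0L)
  set.seed(6)
  y <- rgamma(365, 2, scale = 8)
  expect_equal(pm25_exceedance(y)$exceedance_days, sum(y > 27))
  expect_warning(na <- pm25_exceedance(rep(NA_real_, 5)), "all-missing")
  expect_true(is.na(na$exceedance_days))
})
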