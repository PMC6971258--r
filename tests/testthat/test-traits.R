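test_that("fro_volume sums ellipsoid volumes", {
  expect_identical(fro_volume(numeric(0), numeric(0), numeric(0)), 0)
  expect_equal(fro_volume(1, 1, 1), 4 * pi / 3)
  expect_equal(fro_volume(c(1, 2), c(2, 2), c(3, 2)), 4 / 3 * pi * 14)
})

test_that("fro_volume is additive over disjoint organ sets", {
  set.seed(1)
  for (i in 1:20) {
    a <- runif(6, 0, 40); b <- runif(6, 0, 40); c <- runif(6, 0, 60)
    split <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    expect_equal(fro_volume(a, b, c),
                 fro_volume(a[split], b[split], c[split]) +
                   fro_volume(a[!split], b[!split], c[!split]))
  }
})

test_that("fro_volume rejects negative dimensions, naming the organ", {
  expect_error(fro_volume(c(1, -2), c(1, 1), c(1, 1),
                          organ_id = c("o1", "o2")), "o2")
})

test_that("fro_growth divides volume change by actual day gaps", {
  d1 <- as.Date("2014-01-10"); d2 <- as.Date("2014-02-09")
  expect_equal(fro_growth(100, 100, d2, d1), 0)
  expect_equal(fro_growth(160, 100, d2, d1), 2)
  expect_equal(fro_growth(40, 100, d2, d1), -2)
  # antisymmetry in the volumes
  expect_equal(fro_growth(130, 70, d2, d1), -fro_growth(70, 130, d2, d1))
  expect_error(fro_growth(1, 2, d1, d2), "strictly later")
})

test_that("stem_nsc_average averages three heights, tolerating gaps", {
  expect_equal(stem_nsc_average(3, 3, 3), 3)
  expect_equal(stem_nsc_average(1, 2, 6), 3)
  x <- 2.5; y <- 7
  expect_equal(stem_nsc_average(x, x, y), (2 * x + y) / 3)
  expect_warning(out <- stem_nsc_average(4, NA, 6), "partial")
  expect_equal(out, 5)
  expect_true(is.na(suppressWarnings(stem_nsc_average(NA, NA, NA))))
})

test_that("temperature gaps are bridged by the flanking present values", {
  clim <- data.frame(date = as.Date("2015-05-01") + 0:2,
                     tmax = c(25, NA, 27), tmin = c(20, NA, 22))
  filled <- fill_missing_temperature(clim)
  expect_equal(filled$tmax, c(25, 26, 27))
  expect_equal(filled$tmin, c(20, 21, 22))
  expect_equal(filled$tavg, (filled$tmax + filled$tmin) / 2)

  # a 16-day run, mirroring a mid-May to late-May outage
  clim2 <- data.frame(date = as.Date("2015-05-11") + 0:17,
                      tmax = c(30, rep(NA, 16), 32),
                      tmin = c(22, rep(NA, 16), 24))
  filled2 <- fill_missing_temperature(clim2)
  expect_equal(filled2$tmax, c(30, rep(31, 16), 32))

  # identity on complete data and idempotence
  expect_equal(fill_missing_temperature(filled2), filled2)
  clim3 <- data.frame(date = clim$date, tmax = 25:27, tmin = 20:22)
  expect_equal(fill_missing_temperature(clim3)$tmax, 25:27)

  expect_error(fill_missing_temperature(
    data.frame(date = clim$date, tmax = c(NA, 26, 27),
               tmin = c(20, 21, 22))), "boundary")
})

test_that("cumulative series sum the n days ending on each sampling date", {
  days <- seq(as.Date("2014-01-01"), as.Date("2014-03-01"), by = "day")
  clim <- data.frame(date = days, tavg = rep(25, length(days)),
                     rain = rep(0, length(days)))
  sdates <- as.Date(c("2014-02-10", "2014-03-01"))
  expect_equal(cumulative_series(clim, "CT", 1, sdates)$value, c(25, 25))
  expect_equal(cumulative_series(clim, "CT", 10, sdates)$value, c(250, 250))
  expect_equal(cumulative_series(clim, "CR", 17, sdates)$value, c(0, 0))
  expect_error(cumulative_series(clim, "CT", 45, sdates), "missing dates")
})

test_that("cumulative windows decompose: n = p + q", {
  set.seed(7)
  days <- seq(as.Date("2014-01-01"), by = "day", length.out = 120)
  clim <- data.frame(date = days, tavg = rnorm(120, 27, 2))
  sdates <- days[c(70, 95, 120)]
  p <- 12; q <- 19
  whole <- cumulative_series(clim, "CT", p + q, sdates)$value
  recent <- cumulative_series(clim, "CT", p, sdates)$value
  older <- cumulative_series(clim, "CT", q, sdates - p)$value
  expect_equal(whole, recent + older)
})

test_that("day length follows solar geometry", {
  equinox <- as.Date("2015-03-20")
  expect_lt(abs(day_length(45, equinox) - 12), 0.2)
  expect_lt(abs(day_length(5.14, as.Date("2015-07-10")) - 12), 1)
  expect_lt(abs(day_length(0, as.Date("2015-12-21")) - 12), 0.2)
  year <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  dl <- day_length(5.14, year)
  expect_lt(max(dl) - min(dl), 1)            # equatorial amplitude < 1 h
  oracle <- noaa_day_length(5.14, year)
  expect_lt(max(abs(dl - oracle)), 0.15)     # NOAA solar-position oracle
  expect_error(day_length(70, equinox), "latitude")
})

test_that("trait_dataset assembles aligned per-tree series", {
  dates <- as.Date(c("2013-01-10", "2013-02-12", "2013-03-10"))
  organs <- data.frame(tree_id = "t1", date = rep(dates, c(2, 1, 0))[1:3],
                       organ_id = c("o1", "o2", "o1"),
                       stage = "bud", a = c(1, 2, 3), b = c(1, 2, 3),
                       c = c(1, 2, 3))
  nsc <- expand.grid(tree_id = "t1", date = dates,
                     height = c("top", "middle", "bottom"),
                     stringsAsFactors = FALSE)
  nsc$starch <- 10; nsc$sugar <- rep(c(3, 6, 9), 3)  # by date, all heights
  d <- trait_dataset(organs, nsc, treatments = c(t1 = "PFT"))
  expect_s3_class(d, "trait_dataset")
  expect_equal(nrow(d), 3)
  expect_equal(d$treatment, rep("PFT", 3))
  expect_equal(d$V[1], fro_volume(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(d$V[3], 0)                    # no organs -> observed absence
  expect_true(is.na(d$G[1]))
  expect_equal(d$G[2], (d$V[2] - d$V[1]) / as.numeric(dates[2] - dates[1]))
  expect_equal(d$starch, rep(10, 3))
  expect_equal(d$sugar, c(3, 6, 9))
  # configurable handling of organ-free dates
  d2 <- trait_dataset(organs, nsc, empty_fro = NA)
  expect_true(is.na(d2$V[3]))
})
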