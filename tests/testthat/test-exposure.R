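make_series <- function(values, start_hour = 0, day = "2019-05-01",
                        ...) {
  ts <- as.POSIXct(sprintf("%s %02d:00:00", day, start_hour), tz = "UTC") +
    3600 * (seq_along(values) - 1)
  hourly_series(ts, values, ...)
}

test_that("AOT40 accumulates exceedances in the daylight window only", {
  # all below threshold
  s0 <- make_series(rep(35, 24))
  expect_equal(aot40(s0)$aot40_nl_l_h, 0)

  # hand sum: (50, 60, 30) in-window -> 10 + 20 + 0 = 30
  vals <- rep(0, 24)
  vals[8:10] <- c(50, 60, 30)   # hour starts 07, 08, 09
  s1 <- make_series(vals)
  expect_equal(aot40(s1)$aot40_nl_l_h, 30)

  # values outside 7-15 h never contribute
  vals2 <- vals; vals2[1] <- 500; vals2[20] <- 500
  expect_equal(aot40(make_series(vals2))$aot40_nl_l_h, 30)

  # additivity over disjoint segments
  set.seed(9)
  two_days <- make_series(runif(48, 0, 90))
  d1 <- make_series(two_days$o3_nl_l[1:24])
  d2 <- make_series(two_days$o3_nl_l[25:48], day = "2019-05-02")
  expect_equal(aot40(two_days)$aot40_nl_l_h,
               aot40(d1)$aot40_nl_l_h + aot40(d2)$aot40_nl_l_h)

  # missing hours are skipped and reported
  vals3 <- vals; vals3[9] <- NA
  a <- aot40(make_series(vals3))
  expect_equal(a$aot40_nl_l_h, 10)
  expect_equal(a$n_missing, 1)

  # a series with no in-window hours errors
  s_night <- make_series(rep(50, 3), start_hour = 0)
  expect_error(aot40(s_night), "no in-window hours")
})

test_that("window and daily means follow their definitions", {
  s <- make_series(rep(40, 24))
  expect_equal(window_mean(s), 40)
  expect_equal(daily_mean(s), 40)

  s2 <- make_series(c(30, 50), start_hour = 7)
  expect_equal(window_mean(s2), 40)

  # elevated only in the window -> window mean >= daily mean
  vals <- rep(10, 24); vals[8:15] <- 80
  s3 <- make_series(vals)
  expect_gte(window_mean(s3), daily_mean(s3))
})

test_that("filtration efficiency and percent differences", {
  expect_equal(round(filtration_efficiency(21.7, 41.3), 1), 47.5)
  expect_equal(filtration_efficiency(30, 30), 0)
  expect_equal(filtration_efficiency(0, 41.3), 100)
  expect_error(filtration_efficiency(10, 0), "> 0")

  expect_equal(round(percent_difference(64.6, 41.3), 1), 56.4)
  expect_equal(percent_difference(19.1, 15.8, "absolute"), 3.3)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "nonzero")
})

test_that("VPD uses the Magnus form applied per record", {
  expect_equal(vpd_from_t_rh(25, 100), 0)
  # t = 20, rh = 50: es = 0.6108 exp(17.27*20/257.3) ~ 2.339 kPa
  expect_equal(vpd_from_t_rh(20, 50), 1.169, tolerance = 2e-3)
  # strictly increasing in t at fixed rh < 100
  v <- vpd_from_t_rh(seq(5, 35, by = 5), 60)
  expect_true(all(diff(v) > 0))
  expect_error(vpd_from_t_rh(20, 120), "\\[0, 100\\]")

  # mean of hourly VPD differs from VPD of the means (nonlinearity)
  t_c <- c(10, 30); rh <- c(80, 40)
  s <- make_series(c(50, 50), start_hour = 7, t_c = t_c, rh_pct = rh)
  expect_equal(mean_vpd(s), mean(vpd_from_t_rh(t_c, rh)))
  expect_false(isTRUE(all.equal(mean_vpd(s),
                                vpd_from_t_rh(mean(t_c), mean(rh)))))
})

test_that("series validation and CSV round-trip", {
  ts <- as.POSIXct("2019-05-01 00:00:00", tz = "UTC") + 3600 * 0:5
  expect_error(hourly_series(ts[c(1, 3, 5)], c(1, 2, 3)), "hourly")
  expect_error(hourly_series(ts, rep(-1, 6)), ">= 0")

  f <- withr::local_tempfile(fileext = ".csv")
  s <- make_series(runif(24, 0, 80), t_c = runif(24, 10, 25),
                   rh_pct = runif(24, 30, 90))
  utils::write.csv(data.frame(timestamp = format(s$timestamp,
                                                 "%Y-%m-%d %H:%M:%S"),
                              o3_nl_l = s$o3_nl_l, t_c = s$t_c,
                              rh_pct = s$rh_pct),
                   f, row.names = FALSE)
  s2 <- read_series_csv(f)
  expect_equal(s2$o3_nl_l, s$o3_nl_l)
  expect_equal(window_mean(s2), window_mean(s))
})

test_that("chamber-effect arithmetic recomputes the reference comparisons", {
  tab <- chamber_effect_summary()
  val <- function(q) tab$value[tab$quantity == q]
  expect_equal(round(val("filtration_efficiency_cfa"), 1), 47.5)
  expect_equal(round(val("o3_nfa_vs_amb"), 1), -2.9)
  expect_equal(round(val("o3_fuplus_vs_amb"), 1), 56.4)
  expect_equal(val("delta_mean_t"), 3.3)
  expect_equal(val("delta_rh"), 4)
  expect_equal(round(val("vpd_otc_vs_ambient")), 36)
  expect_equal(round(val("par_otc_vs_ambient")), -17)
})

test_that("simulated ozone series hit their window mean by construction", {
  s <- simulate_o3_series(days = 5, window_mean_target = 40)
  expect_equal(window_mean(s), 40, tolerance = 1e-12)

  # constant profile at 21.7 never crosses the 40 threshold
  s2 <- simulate_o3_series(days = 37, window_mean_target = 21.7,
                           shape = "constant")
  expect_equal(aot40(s2)$aot40_nl_l_h, 0)

  # diurnal profile: AOT40 matches the closed-form expectation of the shape
  target <- 64.6; days <- 37; amp <- 0.5
  s3 <- simulate_o3_series(days = days, window_mean_target = target,
                           amplitude = amp)
  h <- 0:23
  p <- 1 + amp * cos(2 * pi * (h - 13) / 24)
  conc <- target * p / mean(p[h >= 7 & h < 15])
  expected <- days * sum(pmax(conc[h >= 7 & h < 15] - 40, 0))
  expect_equal(aot40(s3)$aot40_nl_l_h, expected, tolerance = 1e-9)

  expect_error(simulate_o3_series(5, -1), ">= 0")
})
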