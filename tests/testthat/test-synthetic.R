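# Synthetic-data generator: calibration identities, determinism, and
# closed-form moment checks.

test_that("response calibration identities hold to machine precision", {
  grid <- expand.grid(mmt = c(6, 12, 18, 24.5), rm25 = c(1.01, 1.5, 2),
                      rm0 = c(1, 1.3, 2.5))
  for (i in seq_len(nrow(grid))) {
    sc <- cell_scenario(true_mmt = grid$mmt[i], true_rm25 = grid$rm25[i],
                        true_rm0 = grid$rm0[i])
    f <- temp_response(sc)
    expect_identical(f(sc$true_mmt), 0)
    expect_equal(exp(f(25) - f(sc$true_mmt)), sc$true_rm25,
                 tolerance = 1e-12)
    expect_equal(exp(f(0) - f(sc$true_mmt)), sc$true_rm0,
                 tolerance = 1e-12)
  }
})

test_that("scenario invariants are enforced", {
  expect_error(cell_scenario(true_mmt = 25), "true_mmt")
  expect_error(cell_scenario(true_mmt = 5), "true_mmt")
  expect_error(cell_scenario(true_rm25 = 2.5), "true_rm25")
  expect_error(cell_scenario(base_rate = 0), "base_rate")
  expect_error(cell_scenario(ar1_rho = 1), "ar1_rho")
  expect_error(cell_scenario(dow_effects = rep(0.1, 7)), "dow_effects")
})

test_that("temperature generator: degenerate and sinusoid cases", {
  dates <- seq(as.Date("1991-01-01"), as.Date("1991-12-31"), by = "day")
  sc0 <- cell_scenario(mean_annual_temp = 15, seasonal_amplitude = 0,
                       warming_per_decade = 0, noise_sd = 0)
  expect_equal(gen_temperature(sc0, dates, 1), rep(15, 365))

  sc1 <- cell_scenario(mean_annual_temp = 12, seasonal_amplitude = 8,
                       warming_per_decade = 0, noise_sd = 0)
  tm <- gen_temperature(sc1, dates, 1)
  # discrete daily sampling misses the exact trough by < 2e-4
  expect_equal(max(tm) - min(tm), 16, tolerance = 5e-5)

  expect_error(gen_temperature(sc1, as.Date(character(0)), 1), "empty")
  expect_error(gen_temperature(sc1, dates[c(1, 3)], 1), "contiguous")
})

test_that("summer mean matches the closed-form seasonal mean", {
  sc <- cell_scenario()
  dates <- seq(as.Date("1968-01-01"), by = "day",
               length.out = round(14 * 365.25))
  tm <- gen_temperature(sc, dates, 1)
  mo <- as.POSIXlt(dates)$mon + 1
  jja <- mo %in% 6:8
  # deterministic part averaged directly over the JJA days
  doy <- as.POSIXlt(dates)$yday + 1
  det <- sc$mean_annual_temp +
    sc$warming_per_decade * (as.numeric(dates - dates[1]) / 365.25) / 10 +
    sc$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  expected <- mean(det[jja])
  # AR(1) stationary sd with autocorrelation-inflated effective n
  sd_st <- sc$noise_sd / sqrt(1 - sc$ar1_rho^2)
  se <- sd_st * sqrt((1 + sc$ar1_rho) / (1 - sc$ar1_rho) / sum(jja))
  expect_lt(abs(mean(tm[jja]) - expected), 3 * se)
})

test_that("covariate generator: support, determinism, pressure mean", {
  dates <- seq(as.Date("1968-01-01"), by = "day", length.out = 10000)
  cov <- gen_covariates(dates, 2)
  expect_true(all(cov$precip >= 0))
  expect_identical(cov, gen_covariates(dates, 2))
  expect_false(identical(cov$pressure, gen_covariates(dates, 3)$pressure))
  sd_st <- 4 / sqrt(1 - 0.9^2)
  se <- sd_st * sqrt((1 + 0.9) / (1 - 0.9) / 10000)
  expect_lt(abs(mean(cov$pressure) - 1013), 3 * se)
})

test_that("death generator: Poisson sum concentration under a flat response", {
  sc <- cell_scenario(base_rate = 3, true_rm25 = 1, true_rm0 = 1,
                      secular_slope = 0)
  dates <- seq(as.Date("1968-01-01"), by = "day", length.out = 5110)
  tm <- gen_temperature(sc, dates, 1)
  y <- gen_deaths(tm, sc, dates, 3)
  expect_true(all(y >= 0), all(y == round(y)))
  expect_lt(abs(sum(y) - 3 * 5110), 4 * sqrt(3 * 5110))
})

test_that("panel generator: calendar length, determinism, spatial signal", {
  p1 <- make_panel(1, 1, seed = 5, start_date = as.Date("1969-01-01"))
  expect_equal(nrow(p1$panel), 365)
  p1l <- make_panel(1, 1, seed = 5, start_date = as.Date("1968-01-01"))
  expect_equal(nrow(p1l$panel), 366)  # leap year

  a <- make_panel(4, 2, seed = 7)
  b <- make_panel(4, 2, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$panel$deaths,
                         make_panel(4, 2, seed = 8)$panel$deaths))
  expect_true(all(is.finite(a$panel$tmean)))
  expect_true(all(a$panel$deaths >= 0))
  expect_true(all(!(a$panel$hw == 1 & a$panel$cs == 1)))

  # the built-in south-north gradient gives spatially structured truth
  p16 <- make_panel(16, 1, seed = 1)
  mi <- morans_i(cbind(p16$truth$lon, p16$truth$lat), p16$truth$true_mmt,
                 n_perm = 999, perm_seed = 1)
  expect_gt(mi$I, 0)
  expect_lt(mi$p_perm, 0.05)
})

test_that("adaptation panels carry per-period truth", {
  p <- make_panel(4, 6, seed = 2,
                  adaptation = list(delta_mmt = 0.8, rm25_start = 1.2,
                                    rm25_end = 1.14))
  expect_equal(p$truth$true_mmt_p3 - p$truth$true_mmt_p1, rep(0.8, 4))
  expect_equal(p$truth$true_rm25_p2, rep(1.17, 4))
})
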