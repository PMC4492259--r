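# Penalized IRLS, the UBRE score and smoothing-parameter selection.

smooth_design <- function(x, df) {
  b <- crs_basis(x, place_knots(x, df))
  con <- center_constraint(b$X, b$S)
  list(X = cbind(1, con$X),
       pen = list(list(idx = 1 + seq_len(ncol(con$X)), S = con$S)))
}

test_that("intercept-only fit reproduces the sample mean and GLM deviance", {
  set.seed(1)
  y <- rpois(400, 4)
  f <- pirls_fit(matrix(1, 400, 1), list(), numeric(0), y)
  expect_equal(unique(round(f$fitted, 10)), mean(y), tolerance = 1e-9)
  expect_equal(f$deviance, glm(y ~ 1, family = poisson)$deviance,
               tolerance = 1e-10)
  expect_equal(f$edf, 1, tolerance = 1e-8)
  expect_error(pirls_fit(matrix(1, 4, 1), list(), numeric(0), c(1, -1, 0, 2)),
               "non-negative")
})

test_that("infinite smoothing recovers the linear-term Poisson GLM", {
  set.seed(2)
  for (r in 1:3) {
    n <- 250
    x <- runif(n)
    y <- rpois(n, exp(1 + 0.7 * x))
    d <- smooth_design(x, 5)
    f <- pirls_fit(d$X, d$pen, 1e10, y)
    g <- glm(y ~ x, family = poisson)
    expect_lt(abs(f$deviance - g$deviance) / g$deviance, 1e-6)
    expect_equal(f$edf, 2, tolerance = 1e-3)
  }
})

test_that("unpenalized spline nests any linear fit; score equation holds", {
  set.seed(3)
  x <- runif(300)
  y <- rpois(300, exp(1 + sin(3 * x)))
  d <- smooth_design(x, 6)
  f0 <- pirls_fit(d$X, d$pen, 0, y)
  g <- glm(y ~ x, family = poisson)
  expect_lte(f0$deviance, g$deviance)
  expect_lt(abs(sum(f0$fitted) - sum(y)) / sum(y), 1e-6)
})

test_that("EDF decreases as lambda grows", {
  set.seed(4)
  x <- runif(300)
  y <- rpois(300, exp(1 + sin(3 * x)))
  d <- smooth_design(x, 6)
  edfs <- vapply(c(0, 1e-2, 1, 1e2, 1e4, 1e8),
                 function(l) pirls_fit(d$X, d$pen, l, y)$edf, numeric(1))
  expect_true(all(diff(edfs) < 1e-8))
})

test_that("UBRE score identities", {
  f <- list(deviance = 120, edf = 7, n_obs = 1000)
  expect_equal(ubre_score(f), 120 / 1000 - 1 + 2 * 7 / 1000)
  # halved deviance at fixed EDF lowers the score by D/(2n)
  f2 <- f; f2$deviance <- 60
  expect_equal(ubre_score(f) - ubre_score(f2), 120 / 2 / 1000)
  # saturated-fit limit: D -> 0, EDF -> n gives score -> +1
  expect_equal(ubre_score(list(deviance = 0, edf = 1000, n_obs = 1000)), 1)
  expect_error(ubre_score(list(deviance = 1, edf = 1, n_obs = 0)), "obs")
})

test_that("lambda selection is deterministic and adapts to curvature", {
  set.seed(5)
  n <- 600
  x <- runif(n)
  # straight-line truth: heavy smoothing wins
  y_lin <- rpois(n, exp(0.8 + 0.9 * x))
  d <- smooth_design(x, 6)
  s1 <- select_lambda(d$X, d$pen, y_lin)
  s2 <- select_lambda(d$X, d$pen, y_lin)
  expect_identical(s1$lambda, s2$lambda)
  expect_gte(log10(s1$lambda), 3)  # at or near the top of the grid
  g <- glm(y_lin ~ x, family = poisson)
  expect_lt(s1$fit$deviance, 2 * g$deviance)

  # strongly curved truth: smoothing backs off, beats the linear fit
  y_cur <- rpois(n, exp(1 + sin(2 * pi * x)))
  s3 <- select_lambda(d$X, d$pen, y_cur)
  expect_lt(log10(s3$lambda), 6)
  expect_lt(s3$fit$deviance, glm(y_cur ~ x, family = poisson)$deviance)
})

test_that("fits agree with an independent penalized-spline implementation", {
  skip_if_not_installed("mgcv")
  d <- quick_cell_data(n_years = 2, seed = 10, base_rate = 5)
  fit <- fit_model(d)
  fl <- label_extremes(d$tmean)
  md <- data.frame(deaths = d$deaths, tmean = d$tmean, precip = d$precip,
                   pressure = d$pressure, tt = seq_len(nrow(d)),
                   dow = factor(mmtgrid:::day_of_week(d$date)),
                   hw = fl$hw, cs = fl$cs)
  m <- mgcv::gam(deaths ~ s(tmean, bs = "cr", k = 6) +
                   s(precip, bs = "cr", k = 4) +
                   s(pressure, bs = "cr", k = 4) +
                   s(tt, bs = "cr", k = 3) + dow + hw + cs,
                 family = poisson, data = md, method = "GCV.Cp", scale = 1)
  # both UBRE optimisations should land on near-identical fits
  expect_equal(fit$deviance, deviance(m), tolerance = 0.02)
  tg <- curve_grid()
  pr <- mgcv::predict.gam(m, newdata = data.frame(
    tmean = tg, precip = 0, pressure = 1013, tt = 1,
    dow = factor(1, levels = 1:7), hw = 0, cs = 0), type = "terms")
  s1_ref <- pr[, "s(tmean)"]
  s1_own <- eval_curve(fit)
  expect_lt(abs(extract_mmt(s1_own) - tg[which.min(s1_ref)]), 0.5)
})
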