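# Period splitting, summaries, Wilcoxon shifts, the MST-MMT regression
# and the annual minimum-mortality date.

test_that("period splitting partitions the panel", {
  specs <- period_specs(1968, 3, 14)
  expect_equal(specs$start, as.Date(c("1968-01-01", "1982-01-01",
                                      "1996-01-01")))
  expect_equal(specs$end, as.Date(c("1981-12-31", "1995-12-31",
                                    "2009-12-31")))
  dates <- seq(specs$start[1], specs$end[3], by = "day")
  panel <- data.frame(date = dates, v = seq_along(dates))
  parts <- split_periods(panel, specs)
  expect_equal(sum(vapply(parts, nrow, integer(1))), length(dates))
  # boundary day belongs to its own period
  expect_true(as.Date("1981-12-31") %in% parts$P1$date)
  expect_false(as.Date("1982-01-01") %in% parts$P1$date)
  # brute-force interval check on random dates
  set.seed(14)
  idx <- sample(length(dates), 200)
  for (i in idx) {
    hit <- names(parts)[vapply(seq_len(3), function(k)
      dates[i] >= specs$start[k] & dates[i] <= specs$end[k], logical(1))]
    expect_true(dates[i] %in% parts[[hit]]$date)
  }
  bad <- specs; bad$start[2] <- bad$start[2] + 5
  expect_error(split_periods(panel, bad), "contiguous")
})

test_that("days above the MMT are counted strictly", {
  expect_equal(days_above_mmt(c(10, 20, 25), 30), 0)
  expect_equal(days_above_mmt(c(10, 20, 25), 5), 3)
  expect_equal(days_above_mmt(c(10, 20, 25), 20), 1)  # strict
  set.seed(15)
  tm <- rnorm(500, 15, 8)
  expect_equal(days_above_mmt(tm, 17.3), sum(tm > 17.3))
  expect_error(days_above_mmt(tm, NA), "finite")
})

test_that("period summaries are means and sample SDs over cells", {
  syn <- make_panel(4, 1, seed = 16, base_rate = 5)
  curves <- data.frame(cell_id = unique(syn$panel$cell_id),
                       period_id = "P1", mmt = c(17, 19, 18, 16),
                       rm25 = c(1.1, 1.2, 1.15, 1.18),
                       rm25_18 = c(1.1, 1.19, 1.14, 1.17))
  out <- summarize_period(curves, syn$panel)
  expect_equal(out$mmt_mean, 17.5)
  expect_equal(out$mmt_sd, sd(c(17, 19, 18, 16)))
  # independent recomputation of each climate column
  for (i in 1:4) {
    ci <- syn$panel[syn$panel$cell_id == curves$cell_id[i], ]
    mo <- as.POSIXlt(ci$date)$mon + 1
    expect_equal(out$mst_mean,
                 mean(vapply(curves$cell_id, function(cl) {
                   cj <- syn$panel[syn$panel$cell_id == cl, ]
                   mean(cj$tmean[(as.POSIXlt(cj$date)$mon + 1) %in% 6:8])
                 }, numeric(1))), tolerance = 1e-10)
  }
  # two cells with MMT 17 and 19
  two <- curves[1:2, ]
  out2 <- summarize_period(two, syn$panel)
  expect_equal(out2$mmt_mean, 18)
  expect_equal(out2$mmt_sd, sqrt(2))
  expect_message(summarize_period(curves[1, ], syn$panel), "single")
  expect_error(summarize_period(curves[0, ], syn$panel), "no eligible")
})

test_that("Wilcoxon signed-rank: closed forms, symmetry, exhaustive oracle", {
  w <- wilcoxon_signed_rank(rep(0, 5), 1:5)
  expect_equal(w$W, 15)
  expect_equal(w$p, 1 / 16)
  w_neg <- wilcoxon_signed_rank(1:5, rep(0, 5))
  expect_equal(w_neg$p, w$p)

  set.seed(17)
  d <- round(rnorm(8, 0.3, 1), 3)  # distinct, no zeros
  w8 <- wilcoxon_signed_rank(rep(0, 8), d)
  # brute force over all 2^8 sign assignments
  r <- rank(abs(d))
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  null_W <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  p_bf <- min(1, 2 * min(mean(null_W >= w8$W), mean(null_W <= w8$W)))
  expect_equal(w8$p, p_bf, tolerance = 1e-12)
  ref <- suppressWarnings(wilcox.test(d, exact = TRUE))
  expect_equal(w8$p, ref$p.value, tolerance = 1e-12)

  # ties force the corrected normal approximation
  dt <- c(1, 1, -1, 2, 2, 3, -2, 4, 5, 5)
  wt <- wilcoxon_signed_rank(rep(0, 10), dt)
  expect_equal(wt$method, "normal")
  ref <- suppressWarnings(wilcox.test(dt, correct = TRUE))
  expect_equal(wt$p, ref$p.value, tolerance = 1e-10)
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "zero")
})

test_that("the MST-MMT regression matches closed forms", {
  mst <- c(14, 16, 18, 20, 22)
  reg <- suppressWarnings(spatial_regression(0.75 * mst + 3, mst))
  expect_equal(reg$slope, 0.75, tolerance = 1e-12)
  expect_equal(reg$ci[2] - reg$ci[1], 0, tolerance = 1e-9)
  expect_equal(reg$r, 1, tolerance = 1e-12)

  set.seed(18)
  mst <- rnorm(40, 18, 1.5)
  mmt <- 0.7 * mst + rnorm(40, 0, 0.5)
  reg <- spatial_regression(mmt, mst)
  # textbook formulas
  bhat <- cov(mst, mmt) / var(mst)
  expect_equal(reg$slope, bhat, tolerance = 1e-12)
  res <- mmt - (mean(mmt) - bhat * mean(mst)) - bhat * mst
  se <- sqrt(sum(res^2) / 38 / sum((mst - mean(mst))^2))
  expect_equal(reg$ci, bhat + qt(c(0.025, 0.975), 38) * se,
               tolerance = 1e-10)
  expect_equal(reg$r, cor(mmt, mst), tolerance = 1e-12)
  expect_error(spatial_regression(1:5, rep(3, 5)), "variance")
})

test_that("predicted MMT change is linear in the MST change", {
  p <- predicted_mmt_change(0.69, c(0.58, 0.79), 1.6)
  expect_equal(p$point, 1.1)
  expect_equal(p$ci, c(0.9, 1.3))
  expect_equal(predicted_mmt_change(0.69, c(0.58, 0.79), 0)$point, 0)
  p2 <- predicted_mmt_change(0.5, c(0.4, 0.6), 2)
  expect_equal(p2$point_raw, 2 * 0.5)
  expect_equal(predicted_mmt_change(0.5, c(0.4, 0.6), 4)$point_raw,
               2 * p2$point_raw)
})

test_that("sociodemographic correlations average census years", {
  mmt <- rnorm(50, 18, 1)
  sc <- sociodemo_correlations(mmt, mmt * 2, mmt * 2)
  expect_equal(sc$r, 1, tolerance = 1e-12)
  set.seed(19)
  # null covariate: |r| small in most replicates at n = 200
  small <- 0
  for (r in 1:20) {
    m <- rnorm(200); cv1 <- rnorm(200); cv2 <- rnorm(200)
    small <- small + (abs(sociodemo_correlations(m, cv1, cv2)$r) < 0.2)
  }
  expect_gte(small / 20, 0.9)
  # direct formula
  y1 <- rnorm(30); y2 <- rnorm(30); m <- rnorm(30)
  expect_equal(sociodemo_correlations(m, y1, y2)$r,
               cor(m, (y1 + y2) / 2), tolerance = 1e-12)
  expect_error(sociodemo_correlations(1:2, 1:2, 2:3), "3 complete")
})

test_that("the annual minimum-mortality date survives smoothing", {
  dates <- seq(as.Date("1969-01-01"), as.Date("1972-12-31"), by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  deaths <- 100 + 30 * cos(2 * pi * (doy - 236 + 182.5) / 365)
  got <- min_mortality_date(dates, deaths)
  expect_equal(got$doy, 236)

  expect_equal(min_mortality_date(dates, rep(7, length(dates)))$doy, 1)

  set.seed(20)
  noisy <- deaths + rnorm(length(deaths), 0, 5)
  got <- min_mortality_date(dates, noisy)
  # brute-force: day-of-year average then circular moving average scan
  md <- format(dates, "%m-%d"); md[md == "02-29"] <- "02-28"
  dd <- as.integer(strftime(as.Date(paste0("2001-", md)), "%j"))
  avg <- tapply(noisy, dd, mean)[as.character(1:365)]
  padded <- c(avg[361:365], avg, avg[1:5])
  sm <- sapply(1:365, function(i) mean(padded[i:(i + 10)]))
  expect_equal(got$doy, which.min(sm))
  expect_error(min_mortality_date(dates[1:100], deaths[1:100]), "full year")
})
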