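# By-period machinery: period splits, Table-1-style cell summaries,
# Wilcoxon signed-rank shift tests, the spatial MST-MMT regression and
# its predicted-vs-observed MMT change, sociodemographic correlations,
# and the annual date of minimum mortality.

#' Define contiguous analysis periods
#'
#' Default layout: three equal 14-year blocks (the 1968-1981, 1982-1995,
#' 1996-2009 design), but any contiguous non-overlapping blocks work.
#'
#' @param start_year First year of the first period.
#' @param n_periods Number of periods.
#' @param years_each Length of each period in years.
#' @param ids Period labels (default P1, P2, ...).
#' @return `data.frame` with columns `period_id`, `start`, `end`.
#' @export
period_specs <- function(start_year = 1968, n_periods = 3, years_each = 14,
                         ids = paste0("P", seq_len(n_periods))) {
  start <- as.Date(sprintf("%d-01-01", start_year + years_each * (seq_len(n_periods) - 1)))
  end <- as.Date(sprintf("%d-12-31", start_year + years_each * seq_len(n_periods) - 1))
  data.frame(period_id = ids, start = start, end = end)
}

#' Split a panel into periods
#'
#' Each day is assigned to the unique period containing its date; the
#' specs must tile the panel without gaps or overlaps.
#'
#' @param panel Long `data.frame` with a `date` column.
#' @param specs A [period_specs()] table.
#' @return Named list of per-period `data.frame`s.
#' @export
split_periods <- function(panel, specs) {
  specs <- specs[order(specs$start), , drop = FALSE]
  if (nrow(specs) > 1L &&
      any(specs$start[-1L] != specs$end[-nrow(specs)] + 1L))
    stop("period specs must be contiguous and non-overlapping")
  dates <- as.Date(panel$date)
  out <- lapply(seq_len(nrow(specs)), function(i)
    panel[dates >= specs$start[i] & dates <= specs$end[i], , drop = FALSE])
  names(out) <- specs$period_id
  if (sum(vapply(out, nrow, integer(1))) !=
      sum(dates >= min(specs$start) & dates <= max(specs$end)))
    stop("period assignment failed")  # nocov
  out
}

#' Count days above the MMT
#'
#' Number of days within a period whose temperature strictly exceeds the
#' cell's MMT.
#'
#' @param temps Daily temperatures of the cell within the period.
#' @param mmt The cell-period MMT (degrees C).
#' @return Integer count.
#' @export
days_above_mmt <- function(temps, mmt) {
  if (!is.finite(mmt)) stop("`mmt` must be finite")
  sum(temps > mmt)
}

#' Summarise one period over the analysis cells
#'
#' Mean and sample standard deviation (n-1; a single cell reports SD 0)
#' across cells of: mean summer and winter temperature, heat-wave and
#' cold-spell days, MMT, days above the MMT, RM25 and RM25/18.  Cells
#' must already be restricted to those eligible and U/J-shaped in all
#' periods.
#'
#' @param curves Curve-summary rows for this period (one per cell), as
#'   from [summarize_curve()].
#' @param climate Per-cell period panel rows (`cell_id`, `date`, `tmean`,
#'   `hw`, `cs`).
#' @return One-row `data.frame` of `<column>_mean` / `<column>_sd` pairs
#'   plus `period_id` and `n_cells`.
#' @export
summarize_period <- function(curves, climate) {
  if (nrow(curves) == 0L) stop("no eligible cells to summarise")
  per_cell <- lapply(seq_len(nrow(curves)), function(i) {
    ci <- climate[climate$cell_id == curves$cell_id[i], , drop = FALSE]
    sm <- seasonal_means(ci$date, ci$tmean)
    data.frame(mst = sm$mst, mwt = sm$mwt, hw_days = sum(ci$hw),
               cs_days = sum(ci$cs), mmt = curves$mmt[i],
               days_above = days_above_mmt(ci$tmean, curves$mmt[i]),
               rm25 = curves$rm25[i], rm25_18 = curves$rm25_18[i])
  })
  tab <- do.call(rbind, per_cell)
  if (nrow(tab) == 1L)
    message("single eligible cell: SDs reported as 0")
  out <- data.frame(period_id = curves$period_id[1L], n_cells = nrow(tab))
  for (cl in names(tab)) {
    out[[paste0(cl, "_mean")]] <- mean(tab[[cl]])
    out[[paste0(cl, "_sd")]] <- sd0(tab[[cl]])
  }
  out
}

#' Wilcoxon signed-rank test for paired shifts
#'
#' Midranks on the absolute differences after dropping zero differences;
#' the statistic is the sum of ranks of positive differences.  The exact
#' null distribution is used for n <= 25 without ties; otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Paired samples (e.g. per-cell MMT at two periods);
#'   differences are `b - a`.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `W`, `n` (non-zero pairs), `p` (two-sided) and
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25L) {
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  if (n < 5L) warning("fewer than 5 non-zero pairs; test has little power")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= exact_max && !ties) {
    # exact: P(W >= w) + P(W <= w), doubled tail, capped at 1
    p_hi <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p_lo <- stats::psignrank(W, n)
    p <- min(1, 2 * min(p_hi, p_lo))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(W = W, n = n, p = p, method = method)
}

#' Regress MMT on mean summer temperature across cells
#'
#' Ordinary least squares of cell MMT on cell MST, with the t-based 95%
#' confidence interval of the slope, Pearson's correlation and its
#' independence-test p-value.
#'
#' @param mmt,mst Per-cell values (n >= 3).
#' @param level Confidence level (default 0.95).
#' @return List with `slope`, `intercept`, `ci` (length 2), `r`, `p`,
#'   `n`.
#' @export
spatial_regression <- function(mmt, mst, level = 0.95) {
  n <- length(mmt)
  stopifnot(length(mst) == n)
  if (n < 3L) stop("need at least 3 cells")
  if (stats::var(mst) == 0) stop("MST has zero variance")
  fit <- stats::lm(mmt ~ mst)
  ci <- stats::confint(fit, "mst", level = level)
  ct <- stats::cor.test(mmt, mst)
  list(slope = unname(stats::coef(fit)["mst"]),
       intercept = unname(stats::coef(fit)[1L]),
       ci = as.numeric(ci), r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Predicted MMT change from the spatial MST-MMT slope
#'
#' Applies the cross-sectional slope to an observed MST change:
#' `point = delta_mst * slope`, with the CI scaled the same way; results
#' are reported at 0.1-degree rounding.
#'
#' @param slope Spatial slope (degrees MMT per degree MST).
#' @param slope_ci Length-2 confidence interval of the slope.
#' @param delta_mst Observed MST change (degrees C).
#' @return List with `point` and `ci`, both rounded to 0.1 C; the
#'   unrounded values are attached as `point_raw` / `ci_raw`.
#' @export
predicted_mmt_change <- function(slope, slope_ci, delta_mst) {
  stopifnot(is.finite(slope), all(is.finite(slope_ci)), is.finite(delta_mst))
  point <- delta_mst * slope
  ci <- delta_mst * sort(slope_ci)
  list(point = round(point, 1), ci = round(ci, 1),
       point_raw = point, ci_raw = ci)
}

#' Correlate MMT with sociodemographic rates
#'
#' For each period the covariate is the mean of the period's two
#' census-year rates; Pearson's correlation with its t-test p-value is
#' computed over complete pairs.
#'
#' @param mmt Named or positional per-cell MMT values.
#' @param rates_y1,rates_y2 Per-cell rates at the period's two census
#'   years (aligned with `mmt`).
#' @return List with `r`, `p`, `n`.
#' @export
sociodemo_correlations <- function(mmt, rates_y1, rates_y2) {
  covar <- (rates_y1 + rates_y2) / 2
  ok <- is.finite(mmt) & is.finite(covar)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs")
  ct <- stats::cor.test(mmt[ok], covar[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Annual date of minimum mortality
#'
#' Aggregates daily deaths over a group of cells, averages them by
#' day-of-year across the period's years (29 February merged into 28
#' February), applies an 11-day centred circular moving average, and
#' returns the day-of-year at which the smoothed series is lowest (ties
#' broken toward the earliest day).
#'
#' @param dates,deaths Daily dates and death counts (possibly several
#'   cells; same dates repeated are summed).
#' @param window Moving-average window (default 11, centred).
#' @return List with `doy` (1-365) and `date_label` ("%d %B" in a
#'   non-leap reference year).
#' @export
min_mortality_date <- function(dates, deaths, window = 11L) {
  if (length(dates) == 0L) stop("empty group")
  dates <- as.Date(dates)
  daily <- tapply(deaths, dates, sum)
  dts <- as.Date(names(daily))
  if (as.numeric(max(dts) - min(dts)) < 364) stop("need at least one full year")
  # Map every date onto a non-leap calendar (29 Feb merged into 28 Feb).
  md <- format(dts, "%m-%d")
  md[md == "02-29"] <- "02-28"
  doy <- as.integer(strftime(as.Date(paste0("2001-", md)), "%j"))
  avg <- tapply(as.numeric(daily), doy, mean)
  series <- as.numeric(avg[order(as.integer(names(avg)))])
  if (length(series) != 365L) stop("period does not cover all days of year")
  sm <- circular_ma(series, window)
  i <- which.min(sm)
  list(doy = i,
       date_label = format(as.Date(i - 1, origin = "2001-01-01"), "%d %B"))
}

# Centred circular moving average of odd width.
circular_ma <- function(x, window) {
  half <- (window - 1L) %/% 2L
  n <- length(x)
  xx <- c(x[(n - half + 1L):n], x, x[1L:half])
  stats::filter(xx, rep(1 / window, window), sides = 2)[(half + 1L):(half + n)]
}
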