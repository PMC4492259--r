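# Heat-wave / cold-spell labelling and seasonal mean temperatures.

#' Label heat-wave and cold-spell days
#'
#' A day is a heat-wave day if it is at least the `min_run`-th day of a
#' maximal consecutive run of days with temperature strictly above the
#' `hi_quantile` empirical quantile of the whole series; cold-spell days
#' are symmetric below the `lo_quantile`.  Thresholds use the
#' linear-interpolation quantile definition.  The first `min_run - 1` days
#' of each run are never flagged, so a run of length L contributes
#' `max(L - min_run + 1, 0)` flagged days.
#'
#' @param temps Daily temperature series; length must be at least
#'   `10 * min_run`.
#' @param hi_quantile,lo_quantile Threshold quantiles (defaults 0.99 and
#'   0.01).
#' @param min_run The first day of a run that gets flagged (default 4).
#' @return `data.frame` with integer 0/1 columns `hw` and `cs`.
#' @export
label_extremes <- function(temps, hi_quantile = 0.99, lo_quantile = 0.01,
                           min_run = 4L) {
  if (min_run < 1L) stop("`min_run` must be >= 1")
  if (!(lo_quantile > 0 && lo_quantile < hi_quantile && hi_quantile < 1))
    stop("need 0 < lo_quantile < hi_quantile < 1")
  if (length(temps) < 10L * min_run)
    stop("series too short to define local extremes")
  hi <- stats::quantile(temps, hi_quantile, names = FALSE, type = 7)
  lo <- stats::quantile(temps, lo_quantile, names = FALSE, type = 7)
  data.frame(hw = run_flags(temps > hi, min_run),
             cs = run_flags(temps < lo, min_run))
}

# Flag positions >= min_run within each maximal run of TRUE.
run_flags <- function(exceed, min_run) {
  r <- rle(exceed)
  pos <- sequence(r$lengths)           # position within each run
  as.integer(rep(r$values, r$lengths) & pos >= min_run)
}

#' Mean summer and winter temperature of a period
#'
#' MST is the mean daily temperature over June-August days, MWT over
#' calendar December, January and February days, within the requested
#' period.
#'
#' @param dates `Date` vector.
#' @param temps Matching temperature series.
#' @param start,end Optional period bounds (inclusive); default is the
#'   whole series.
#' @return Named list with `mst` and `mwt` (degrees C).
#' @export
seasonal_means <- function(dates, temps, start = NULL, end = NULL) {
  dates <- as.Date(dates)
  keep <- rep(TRUE, length(dates))
  if (!is.null(start)) keep <- keep & dates >= as.Date(start)
  if (!is.null(end)) keep <- keep & dates <= as.Date(end)
  if (!any(keep)) stop("empty period selection")
  mo <- as.POSIXlt(dates[keep])$mon + 1L
  t <- temps[keep]
  summer <- mo %in% 6:8
  winter <- mo %in% c(12L, 1L, 2L)
  if (!any(summer) || !any(winter)) stop("period does not cover both seasons")
  list(mst = mean(t[summer]), mwt = mean(t[winter]))
}
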