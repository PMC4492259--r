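# Synthetic multi-cell climate-mortality panels with known ground truth.
#
# Daily mean temperature is seasonal (cosine peaking in mid-July) plus a
# linear warming trend and AR(1) noise.  Death counts are Poisson with a
# log-rate carrying a U/J-shaped temperature response with a known minimum
# (true MMT) and known heat-side ratio at 25 degrees C (true RM25),
# day-of-week offsets and a slow secular trend.  Everything is
# deterministic given a seed, so downstream estimates can be checked
# against the generating truth.

#' Describe one synthetic grid cell
#'
#' A `cell_scenario` bundles the climate and mortality parameters of a
#' single synthetic cell: its mean annual temperature, seasonal amplitude
#' and warming trend; the AR(1) structure of daily temperature noise; and
#' the known ("true") temperature-mortality response used to generate
#' Poisson death counts.  The response is quadratic in each arm around the
#' true minimum mortality temperature, calibrated so that mortality at
#' 25 degrees C is exactly `true_rm25` times mortality at the minimum, and
#' mortality at 0 degrees C exactly `true_rm0` times.
#'
#' @param cell_id Identifier for the cell.
#' @param mean_annual_temp Mean annual temperature, degrees C.
#' @param seasonal_amplitude Amplitude of the seasonal cosine, degrees C.
#' @param warming_per_decade Linear warming trend, degrees C per decade.
#' @param ar1_rho AR(1) coefficient of daily temperature noise, in `[0, 1)`.
#' @param noise_sd Innovation standard deviation of the AR(1) noise,
#'   degrees C.
#' @param base_rate Expected deaths per day at the minimum mortality
#'   temperature (before day-of-week and trend effects); must be positive.
#' @param true_mmt True minimum mortality temperature, strictly between 5
#'   and 25 degrees C.
#' @param true_rm25 True ratio of mortality at 25 degrees C to mortality at
#'   the minimum; in `[1, 2]` (1 gives a flat heat arm, used for null
#'   calibration).
#' @param true_rm0 True ratio of mortality at 0 degrees C to mortality at
#'   the minimum; must be `>= 1`.
#' @param dow_effects Numeric length-7 vector of log-rate day-of-week
#'   offsets (Monday first), summing to zero.
#' @param secular_slope Slow log-rate drift, per decade.
#' @param hw_effect Extra log-rate on heat-wave days (0 disables the term).
#' @return An object of class `cell_scenario`.
#' @examples
#' sc <- cell_scenario("c1", true_mmt = 18, true_rm25 = 1.2)
#' f <- temp_response(sc)
#' exp(f(25) - f(18))  # exactly 1.2
#' @export
cell_scenario <- function(cell_id = "cell1",
                          mean_annual_temp = 13,
                          seasonal_amplitude = 7.5,
                          warming_per_decade = 0.3,
                          ar1_rho = 0.7,
                          noise_sd = 2.5,
                          base_rate = 3,
                          true_mmt = 18,
                          true_rm25 = 1.2,
                          true_rm0 = 1.3,
                          dow_effects = rep(0, 7),
                          secular_slope = 0.05,
                          hw_effect = 0) {
  if (ar1_rho < 0 || ar1_rho >= 1) stop("`ar1_rho` must lie in [0, 1)")
  if (base_rate <= 0) stop("`base_rate` must be positive")
  if (true_mmt <= 5 || true_mmt >= 25)
    stop("`true_mmt` must lie strictly between 5 and 25 degrees C")
  if (true_rm25 < 1 || true_rm25 > 2) stop("`true_rm25` must lie in [1, 2]")
  if (true_rm0 < 1) stop("`true_rm0` must be >= 1")
  if (length(dow_effects) != 7L || abs(sum(dow_effects)) > 1e-8)
    stop("`dow_effects` must be 7 offsets summing to 0")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(
    list(cell_id = cell_id, mean_annual_temp = mean_annual_temp,
         seasonal_amplitude = seasonal_amplitude,
         warming_per_decade = warming_per_decade, ar1_rho = ar1_rho,
         noise_sd = noise_sd, base_rate = base_rate, true_mmt = true_mmt,
         true_rm25 = true_rm25, true_rm0 = true_rm0,
         dow_effects = as.numeric(dow_effects),
         secular_slope = secular_slope, hw_effect = hw_effect),
    class = "cell_scenario")
}

#' @export
print.cell_scenario <- function(x, ...) {
  cat("<cell_scenario>", x$cell_id, "\n",
      sprintf("  climate: mean %.1f C, amplitude %.1f C, warming %.2f C/decade, AR(1) rho %.2f sd %.2f\n",
              x$mean_annual_temp, x$seasonal_amplitude, x$warming_per_decade,
              x$ar1_rho, x$noise_sd),
      sprintf("  mortality: base %.2f deaths/day, MMT %.1f C, RM25 %.3f, RM0 %.3f, secular %.3f/decade\n",
              x$base_rate, x$true_mmt, x$true_rm25, x$true_rm0,
              x$secular_slope), sep = "")
  invisible(x)
}

#' True temperature-mortality log-rate response of a scenario
#'
#' Returns the log-rate function `f(T)` used to generate deaths:
#' `f(T) = b_c * max(MMT - T, 0)^2 + b_h * max(T - MMT, 0)^2` with
#' `b_h = log(true_rm25) / (25 - MMT)^2` and
#' `b_c = log(true_rm0) / MMT^2`, so that `f(MMT) = 0`,
#' `exp(f(25) - f(MMT)) = true_rm25` and `exp(f(0) - f(MMT)) = true_rm0`
#' hold exactly.
#'
#' @param scenario A [cell_scenario()].
#' @param mmt,rm25 Optional overrides of the scenario's true values
#'   (used for time-varying truth); vectors are allowed and are matched
#'   elementwise with the temperatures passed to the returned function.
#' @return A vectorized function of temperature returning the log-rate
#'   contribution, with attributes `b_heat` and `b_cold`.
#' @export
temp_response <- function(scenario, mmt = NULL, rm25 = NULL) {
  mmt <- if (is.null(mmt)) scenario$true_mmt else mmt
  rm25 <- if (is.null(rm25)) scenario$true_rm25 else rm25
  rm0 <- scenario$true_rm0
  b_h <- log(rm25) / (25 - mmt)^2
  b_c <- log(rm0) / mmt^2
  f <- function(temp) {
    b_c * pmax(mmt - temp, 0)^2 + b_h * pmax(temp - mmt, 0)^2
  }
  attr(f, "b_heat") <- b_h
  attr(f, "b_cold") <- b_c
  f
}

#' Generate a daily temperature series
#'
#' Temperature is `mean_annual_temp + warming_per_decade * decades +
#' seasonal_amplitude * cos(2 pi (doy - 196) / 365.25) + AR(1) noise`,
#' peaking around mid-July (day-of-year 196).
#'
#' @param scenario A [cell_scenario()].
#' @param dates Contiguous `Date` vector.
#' @param seed Integer seed; the series is deterministic given the seed.
#' @return Numeric vector of daily mean temperatures (degrees C).
#' @export
gen_temperature <- function(scenario, dates, seed) {
  dates <- check_dates(dates)
  doy <- day_of_year(dates)
  dec <- elapsed_years(dates) / 10
  seasonal <- scenario$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  noise <- with_seed(seed,
                     ar1_series(length(dates), scenario$ar1_rho,
                                scenario$noise_sd))
  scenario$mean_annual_temp + scenario$warming_per_decade * dec +
    seasonal + noise
}

#' Generate daily precipitation and sea-level pressure series
#'
#' Precipitation is a wet-day Bernoulli(0.4) indicator times a
#' Gamma(shape 0.8, scale 5) amount (mm); sea-level pressure is
#' 1013 hPa plus AR(1) noise (rho 0.9, innovation sd 4).
#'
#' @inheritParams gen_temperature
#' @return `data.frame` with columns `date`, `precip` (mm) and
#'   `pressure` (hPa).
#' @export
gen_covariates <- function(dates, seed) {
  dates <- check_dates(dates)
  n <- length(dates)
  with_seed(seed, {
    wet <- stats::rbinom(n, 1L, 0.4)
    amount <- stats::rgamma(n, shape = 0.8, scale = 5)
    pressure <- 1013 + ar1_series(n, 0.9, 4)
    data.frame(date = dates, precip = wet * amount, pressure = pressure)
  })
}

#' Generate daily Poisson death counts
#'
#' Counts are Poisson with
#' `log mu_t = log(base_rate) + f(T_t) + dow_effect + secular_slope *
#' decades` where `f` is the scenario's U/J response (see
#' [temp_response()]).  Passing `mmt` / `rm25` vectors (one value per day)
#' makes the true curve drift over time, which is how adaptation panels
#' are built.
#'
#' @param temps Daily temperature series (degrees C).
#' @param scenario A [cell_scenario()].
#' @param dates Dates matching `temps`.
#' @param seed Integer seed.
#' @param mmt,rm25 Optional per-day overrides of the true MMT / RM25.
#' @param hw Optional 0/1 heat-wave flags; required when the scenario's
#'   `hw_effect` is non-zero.
#' @return Integer vector of daily death counts.
#' @export
gen_deaths <- function(temps, scenario, dates, seed,
                       mmt = NULL, rm25 = NULL, hw = NULL) {
  dates <- check_dates(dates)
  stopifnot(length(temps) == length(dates))
  f <- temp_response(scenario, mmt = mmt, rm25 = rm25)
  eta <- log(scenario$base_rate) + f(temps) +
    scenario$dow_effects[day_of_week(dates)] +
    scenario$secular_slope * (elapsed_years(dates) / 10)
  if (scenario$hw_effect != 0) {
    if (is.null(hw)) stop("`hw` flags required when `hw_effect` != 0")
    eta <- eta + scenario$hw_effect * hw
  }
  mu <- exp(eta)
  if (any(!is.finite(mu))) stop("non-finite expected death rate")
  with_seed(seed, stats::rpois(length(mu), mu))
}

#' Generate a complete multi-cell panel with ground truth
#'
#' Cells are laid out on a regular half-degree lattice.  Scenario
#' parameters vary smoothly with lattice row: southern rows are warmer and
#' carry a higher true MMT (`true_mmt = 0.7 * mean_annual_temp + 8.5`), so
#' spatial statistics computed downstream have real signal.  An optional
#' `adaptation` block makes the true MMT rise and the true RM25 fall in
#' three equal sub-period steps, emulating a population adapting to a
#' warming climate.
#'
#' @param n_cells Number of cells (>= 1).
#' @param n_years Number of whole calendar years (>= 1).
#' @param seed Master seed; all per-cell streams derive from it.
#' @param start_date First day of the panel (default 1968-01-01).
#' @param base_rate Deaths/day at the optimum for every cell.
#' @param true_rm25 Baseline true RM25 shared by all cells.
#' @param adaptation Optional list with `delta_mmt` (total true-MMT rise,
#'   degrees C, applied in steps 0, delta/2, delta across three equal
#'   blocks) and `rm25_start`, `rm25_end` (true RM25 at the first and last
#'   block; the middle block is midway).
#' @param records If `TRUE`, also emulate individual death records
#'   (commune id, age > 65 plus external-cause contamination) for testing
#'   the certificate filter.
#' @param external_fraction Fraction of extra external-cause records added
#'   when `records = TRUE`.
#' @param dots Further arguments passed to [cell_scenario()] for every
#'   cell.
#' @param ... Further per-cell [cell_scenario()] arguments.
#' @return A list of class `synthetic_panel` with elements `panel`
#'   (long `data.frame`: date, cell_id, tmean, precip, pressure, deaths,
#'   hw, cs, dow), `truth` (one row per cell: true MMT/RM25/RM0, secular
#'   slope, cell centre coordinates, and per-period truth columns under
#'   adaptation), `grid` (the [build_grid()] lattice) and optionally
#'   `records`.
#' @export
make_panel <- function(n_cells, n_years, seed,
                       start_date = as.Date("1968-01-01"),
                       base_rate = 3, true_rm25 = 1.2,
                       adaptation = NULL, records = FALSE,
                       external_fraction = 0.1, ...) {
  stopifnot(n_cells >= 1L, n_years >= 1L)
  start_date <- as.Date(start_date)
  end_date <- seq(start_date, by = paste(n_years, "years"), length.out = 2L)[2L] - 1L
  dates <- seq(start_date, end_date, by = "day")
  n_cols <- ceiling(sqrt(n_cells))
  n_rows <- ceiling(n_cells / n_cols)
  grid <- build_grid(origin_lon = 0, origin_lat = 42, cell_size = 0.5,
                     n_cols = n_cols, n_rows = n_rows)
  cells <- grid_cells(grid)[seq_len(n_cells), , drop = FALSE]

  # South-to-north climate gradient: row 1 (southern) warmest.
  row_frac <- if (n_rows > 1L) (cells$row - 1) / (n_rows - 1) else rep(0, n_cells)
  col_frac <- if (n_cols > 1L) (cells$col - 1) / (n_cols - 1) - 0.5 else rep(0, n_cells)
  mat <- 16 - 5 * row_frac + 0.4 * col_frac
  mmt <- 0.7 * mat + 8.5

  seeds <- derive_seeds(seed, 3L * n_cells + 1L)
  per_day_mmt <- per_day_rm25 <- NULL
  period_idx <- NULL
  if (!is.null(adaptation)) {
    brk <- ceiling(length(dates) * c(1, 2) / 3)
    period_idx <- findInterval(seq_along(dates) - 1L, brk) + 1L
    mmt_step <- c(0, adaptation$delta_mmt / 2, adaptation$delta_mmt)
    rm25_step <- c(adaptation$rm25_start,
                   (adaptation$rm25_start + adaptation$rm25_end) / 2,
                   adaptation$rm25_end)
  }

  panels <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    sc <- cell_scenario(cell_id = cells$cell_id[i], mean_annual_temp = mat[i],
                        base_rate = base_rate, true_mmt = mmt[i],
                        true_rm25 = if (is.null(adaptation)) true_rm25
                                    else adaptation$rm25_start, ...)
    tmean <- gen_temperature(sc, dates, seeds[3L * i - 2L])
    cov <- gen_covariates(dates, seeds[3L * i - 1L])
    if (!is.null(adaptation)) {
      per_day_mmt <- mmt[i] + mmt_step[period_idx]
      per_day_rm25 <- rm25_step[period_idx]
    }
    flags <- label_extremes(tmean)
    deaths <- gen_deaths(tmean, sc, dates, seeds[3L * i],
                         mmt = per_day_mmt, rm25 = per_day_rm25,
                         hw = flags$hw)
    panels[[i]] <- data.frame(
      date = dates, cell_id = cells$cell_id[i], tmean = tmean,
      precip = cov$precip, pressure = cov$pressure, deaths = deaths,
      hw = flags$hw, cs = flags$cs, dow = day_of_week(dates))
    tr <- data.frame(cell_id = cells$cell_id[i],
                     lon = cells$center_lon[i], lat = cells$center_lat[i],
                     row = cells$row[i], col = cells$col[i],
                     mean_annual_temp = mat[i], true_mmt = mmt[i],
                     true_rm25 = sc$true_rm25, true_rm0 = sc$true_rm0,
                     secular_slope = sc$secular_slope)
    if (!is.null(adaptation)) {
      tr$true_mmt_p1 <- mmt[i]; tr$true_mmt_p2 <- mmt[i] + mmt_step[2]
      tr$true_mmt_p3 <- mmt[i] + mmt_step[3]
      tr$true_rm25_p1 <- rm25_step[1]; tr$true_rm25_p2 <- rm25_step[2]
      tr$true_rm25_p3 <- rm25_step[3]
    }
    truth[[i]] <- tr
  }
  out <- list(panel = do.call(rbind, panels), truth = do.call(rbind, truth),
              grid = grid)
  if (records)
    out$records <- make_records(out$panel, cells, seeds[3L * n_cells + 1L],
                                external_fraction)
  class(out) <- "synthetic_panel"
  out
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d cells x %d days (%s to %s)\n",
              nrow(x$truth), nrow(x$panel) / nrow(x$truth),
              min(x$panel$date), max(x$panel$date)))
  cat(sprintf("  true MMT range %.1f-%.1f C, true RM25 %.2f-%.2f\n",
              min(x$truth$true_mmt), max(x$truth$true_mmt),
              min(x$truth$true_rm25), max(x$truth$true_rm25)))
  invisible(x)
}

# Explode daily counts into synthetic individual certificates: ages > 65,
# natural causes, plus an extra `external_fraction` of external-cause
# records (and a sprinkle of retained heat/cold codes) for filter testing.
make_records <- function(panel, cells, seed, external_fraction) {
  natural10 <- c("I21", "I64", "J18", "C34", "C18", "E11", "F03", "N18")
  natural89 <- c("410", "436", "480", "162", "153", "250", "290", "585")
  external89 <- c("E812", "E880", "E950", "E916")
  external10 <- c("V02", "W10", "X32", "Y20")
  retained89 <- c("E900.0", "E900.9", "E901.0", "E901.8", "E901.9")
  retained10 <- c("X30", "X31")
  with_seed(seed, {
    idx <- rep(seq_len(nrow(panel)), panel$deaths)
    n <- length(idx)
    n_ext <- round(external_fraction * n)
    ext_idx <- if (n_ext > 0) sample(seq_len(nrow(panel)), n_ext, replace = TRUE)
               else integer(0)
    all_idx <- c(idx, ext_idx)
    dates <- panel$date[all_idx]
    cell <- panel$cell_id[all_idx]
    m <- match(cell, cells$cell_id)
    rev <- ifelse(format(dates, "%Y") <= "1978", 8L,
                  ifelse(format(dates, "%Y") <= "1999", 9L, 10L))
    is_ext <- c(rep(FALSE, n), rep(TRUE, n_ext))
    cause <- character(length(all_idx))
    old <- rev < 10L
    cause[!is_ext & old] <- sample(natural89, sum(!is_ext & old),
                                   replace = TRUE)
    cause[!is_ext & !old] <- sample(natural10, sum(!is_ext & !old),
                                    replace = TRUE)
    cause[is_ext & old] <- sample(c(external89, retained89),
                                  sum(is_ext & old), replace = TRUE)
    cause[is_ext & !old] <- sample(c(external10, retained10),
                                   sum(is_ext & !old), replace = TRUE)
    # Four synthetic communes per cell, jittered around the cell centre.
    commune <- paste0(cell, "_c", sample.int(4L, length(all_idx), replace = TRUE))
    data.frame(
      date = dates, commune_id = commune,
      lon = cells$center_lon[m] + stats::runif(length(all_idx), -0.2, 0.2),
      lat = cells$center_lat[m] + stats::runif(length(all_idx), -0.2, 0.2),
      age = 66 + stats::rgamma(length(all_idx), shape = 2, scale = 6),
      icd_rev = rev, cause = cause)
  })
}
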