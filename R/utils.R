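# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n reproducible child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# Stationary AR(1) series: x_t = rho * x_{t-1} + e_t, e_t ~ N(0, sd^2).
# Drawn under the caller's RNG state.
ar1_series <- function(n, rho, sd) {
  stopifnot(n >= 1L)
  if (rho < 0 || rho >= 1) stop("AR(1) parameter must lie in [0, 1)")
  e <- rnorm(n, 0, sd)
  if (sd == 0) return(numeric(n))
  x <- numeric(n)
  x[1L] <- rnorm(1L, 0, sd / sqrt(1 - rho^2))
  if (n > 1L) for (t in 2:n) x[t] <- rho * x[t - 1L] + e[t]
  x
}

# Day-of-year (1..366) and decimal elapsed years since the first date.
day_of_year <- function(dates) as.POSIXlt(dates)$yday + 1L

elapsed_years <- function(dates, origin = dates[1L]) {
  as.numeric(dates - as.Date(origin)) / 365.25
}

# ISO-style day of week: Monday = 1 ... Sunday = 7.
day_of_week <- function(dates) {
  w <- as.POSIXlt(dates)$wday  # 0 = Sunday
  ifelse(w == 0L, 7L, w)
}

check_dates <- function(dates) {
  if (length(dates) == 0L) stop("empty date range")
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("dates contain NA")
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("dates must be contiguous daily values")
  dates
}

# Sample standard deviation with the single-observation convention SD = 0.
sd0 <- function(x) {
  if (length(x) <= 1L) return(0)
  stats::sd(x)
}
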