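# Shared fixtures: small, fast synthetic inputs built in code.

# Daily data for one cell, ready for fit_model().
quick_cell_data <- function(n_years = 2, seed = 1, ...) {
  sc <- cell_scenario(...)
  dates <- seq(as.Date("1990-01-01"), by = "day",
               length.out = round(n_years * 365.25))
  seeds <- mmtgrid:::derive_seeds(seed, 3)
  tm <- gen_temperature(sc, dates, seeds[1])
  cov <- gen_covariates(dates, seeds[2])
  y <- gen_deaths(tm, sc, dates, seeds[3])
  data.frame(date = dates, tmean = tm, precip = cov$precip,
             pressure = cov$pressure, deaths = y)
}

# A curve on the standard lattice from the generator's quadratic-arm
# family.
truth_curve <- function(mmt = 18, rm25 = 1.2, rm0 = 1.3) {
  f <- temp_response(cell_scenario(true_mmt = mmt,
                                   true_rm25 = max(rm25, 1),
                                   true_rm0 = max(rm0, 1)))
  f(curve_grid())
}

# Small regular lattice of centres for spatial tests.
lattice_centers <- function(nr = 4, nc = 4, step = 0.5) {
  as.matrix(expand.grid(lon = step * seq_len(nc), lat = step * seq_len(nr)))
}
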