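# Validation experiments run against synthetic ground truth.  These
# drive both the test suite and the reproduction script: each generates
# its own data from a seed, runs the pipeline, and returns the measured
# quantities.

#' Parameter-recovery experiment
#'
#' Generates independent 14-year cells at 3 deaths/day whose true MMT
#' cycles over 16, 18, 20 degrees C and true RM25 over 1.10, 1.20, fits
#' the temperature-mortality model to each, and measures how well the
#' extracted MMT and RM25 recover the truth.
#'
#' @param n_cells Number of cells (default 20).
#' @param seed Master seed.
#' @param n_years Years of daily data per cell (default 14).
#' @param base_rate Deaths/day at the optimum (default 3).
#' @return List with the per-cell results table and summary measures
#'   `mmt_mae`, `rm25_mae`, `uj_rate`.
#' @export
recovery_experiment <- function(n_cells = 20, seed = 1, n_years = 14,
                                base_rate = 3) {
  true_mmt <- rep(c(16, 18, 20), length.out = n_cells)
  true_rm <- rep(c(1.10, 1.20), length.out = n_cells)
  dates <- seq(as.Date("1968-01-01"),
               by = "day", length.out = round(n_years * 365.25))
  seeds <- derive_seeds(seed, 3L * n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    # climate consistent with the spatial rule mmt = 0.7 * mat + 8.5
    sc <- cell_scenario(cell_id = paste0("cell", i),
                        mean_annual_temp = (true_mmt[i] - 8.5) / 0.7,
                        base_rate = base_rate, true_mmt = true_mmt[i],
                        true_rm25 = true_rm[i])
    tm <- gen_temperature(sc, dates, seeds[3L * i - 2L])
    cov <- gen_covariates(dates, seeds[3L * i - 1L])
    y <- gen_deaths(tm, sc, dates, seeds[3L * i])
    d <- data.frame(date = dates, tmean = tm, precip = cov$precip,
                    pressure = cov$pressure, deaths = y)
    fit <- fit_model(d)
    cv <- eval_curve(fit)
    mmt <- extract_mmt(cv)
    rm <- rm_ratios(cv, mmt)
    rows[[i]] <- data.frame(cell = i, true_mmt = true_mmt[i],
                            mmt = mmt, true_rm25 = true_rm[i],
                            rm25 = rm$rm25, uj = classify_uj(cv))
  }
  tab <- do.call(rbind, rows)
  list(cells = tab,
       mmt_mae = mean(abs(tab$mmt - tab$true_mmt)),
       rm25_mae = mean(abs(tab$rm25 - tab$true_rm25)),
       uj_rate = mean(tab$uj))
}

#' Adaptation-signal experiment
#'
#' Generates a multi-cell panel whose true MMT rises by `delta_mmt`
#' between the first and last 14-year periods while the true RM25 falls,
#' runs the by-period pipeline, and tests whether the extracted summaries
#' recover the adaptation signal.
#'
#' @param n_cells Number of cells (default 12).
#' @param seed Master seed.
#' @param delta_mmt True MMT rise between P1 and P3 (default 0.8 C).
#' @param rm25_start,rm25_end True RM25 at P1 and P3 (1.20, 1.14).
#' @return List with the per-period mean table, paired Wilcoxon p-values
#'   for the P1-vs-P3 shift in MMT, RM25 and RM25/18, and the curve
#'   summaries.
#' @export
adaptation_experiment <- function(n_cells = 12, seed = 1, delta_mmt = 0.8,
                                  rm25_start = 1.20, rm25_end = 1.14) {
  adapt <- list(delta_mmt = delta_mmt, rm25_start = rm25_start,
                rm25_end = rm25_end)
  syn <- make_panel(n_cells, 42, seed, adaptation = adapt)
  cfg <- run_config(n_cells = n_cells, n_years = 42, seed = seed,
                    adaptation = adapt)
  summ <- run_fit(cfg, syn$panel)
  means <- stats::aggregate(cbind(mmt, rm25, rm25_18) ~ period_id,
                            data = summ, FUN = mean)
  cells <- unique(summ$cell_id)
  get <- function(p, v) {
    s <- summ[summ$period_id == p, ]
    s[[v]][match(cells, s$cell_id)]
  }
  tests <- lapply(c(mmt = "mmt", rm25 = "rm25", rm25_18 = "rm25_18"),
                  function(v) wilcoxon_signed_rank(get("P1", v), get("P3", v)))
  list(means = means, tests = tests, summaries = summ, truth = syn$truth)
}

#' Null-calibration experiment
#'
#' Replicated single-cell fits under a flat temperature response (true
#' RM25 = RM0 = 1): the extracted RM25 should concentrate near 1 and the
#' U/J classification should rarely fire.
#'
#' @param n_rep Number of replicates (default 50).
#' @param seed Master seed.
#' @param n_years Years per replicate (default 14).
#' @param base_rate Deaths/day (default 3).
#' @return List with per-replicate `rm25` and `uj` vectors plus
#'   `rm25_mean` and `uj_false_positive_rate`.
#' @export
null_calibration <- function(n_rep = 50, seed = 1, n_years = 14,
                             base_rate = 3) {
  dates <- seq(as.Date("1968-01-01"),
               by = "day", length.out = round(n_years * 365.25))
  seeds <- derive_seeds(seed, 3L * n_rep)
  rm25 <- numeric(n_rep)
  uj <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    sc <- cell_scenario(base_rate = base_rate, true_rm25 = 1, true_rm0 = 1)
    tm <- gen_temperature(sc, dates, seeds[3L * i - 2L])
    cov <- gen_covariates(dates, seeds[3L * i - 1L])
    y <- gen_deaths(tm, sc, dates, seeds[3L * i])
    d <- data.frame(date = dates, tmean = tm, precip = cov$precip,
                    pressure = cov$pressure, deaths = y)
    fit <- fit_model(d)
    cv <- eval_curve(fit)
    rm25[i] <- rm_ratios(cv, extract_mmt(cv))$rm25
    uj[i] <- classify_uj(cv)
  }
  list(rm25 = rm25, uj = uj, rm25_mean = mean(rm25),
       uj_false_positive_rate = mean(uj))
}

#' Smoothing-limit oracle check
#'
#' With every smoothing parameter pushed to 1e10 the penalized spline
#' model collapses to straight lines in each covariate; the fit must then
#' agree with an ordinary Poisson GLM with linear terms.  Runs `n_rep`
#' random small datasets and returns the worst relative deviance gap.
#'
#' @param n_rep Number of random datasets (default 20).
#' @param seed Master seed.
#' @param n Observations per dataset.
#' @return List with per-replicate `gaps` and `max_gap`.
#' @export
glm_limit_check <- function(n_rep = 20, seed = 1, n = 300) {
  seeds <- derive_seeds(seed, n_rep)
  gaps <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    dat <- with_seed(seeds[r], {
      x1 <- stats::runif(n); x2 <- stats::rnorm(n)
      mu <- exp(0.5 + 0.6 * x1 - 0.3 * x2)
      list(x1 = x1, x2 = x2, y = stats::rpois(n, mu))
    })
    b1 <- crs_basis(dat$x1, place_knots(dat$x1, 5))
    c1 <- center_constraint(b1$X, b1$S)
    b2 <- crs_basis(dat$x2, place_knots(dat$x2, 4))
    c2 <- center_constraint(b2$X, b2$S)
    X <- cbind(1, c1$X, c2$X)
    pen <- list(list(idx = 1L + seq_len(ncol(c1$X)), S = c1$S),
                list(idx = 1L + ncol(c1$X) + seq_len(ncol(c2$X)), S = c2$S))
    f <- pirls_fit(X, pen, c(1e10, 1e10), dat$y)
    g <- stats::glm(dat$y ~ dat$x1 + dat$x2, family = stats::poisson())
    gaps[r] <- abs(f$deviance - g$deviance) / g$deviance
  }
  list(gaps = gaps, max_gap = max(gaps))
}
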