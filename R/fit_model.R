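# Model assembly: the daily-mortality Poisson GAM for one grid cell.
#
# log E(Y_t) = s1(T_t) + s2(R_t) + s3(P_t) + s4(t) + alpha*Hw + beta*Cs
#              + gamma*Dow
#
# with penalized cubic regression splines: s1 on daily mean temperature
# (5 df), s2 on precipitation and s3 on sea-level pressure (3 df each),
# s4 on scaled time (1 df per year of data; variants use 2 or 4 df/year).
# The lagged variant adds s1b on the mean temperature of the 6 preceding
# days.  Day of week enters as six contrasts against Monday; heat-wave
# and cold-spell days as 0/1 regressors.

#' Fit the daily temperature-mortality model for one cell
#'
#' @param data `data.frame` for one cell with contiguous daily rows and
#'   columns `date`, `tmean`, `precip`, `pressure`, `deaths`; optional
#'   `hw`, `cs` (computed via [label_extremes()] when absent) and `dow`.
#' @param spec Model variant: `"eq1"` (1 df/year time smooth),
#'   `"eq1_2dfy"` (2 df/year), or `"eq3"` (4 df/year plus a smooth of the
#'   mean temperature over the 6 preceding days; the first 6 days are
#'   dropped from the fit).
#' @param s1_df,s2_df,s3_df Spline degrees of freedom for the
#'   temperature, precipitation and pressure smooths.
#' @param lambda Optional fixed smoothing parameters (one per smooth,
#'   in block order); when `NULL` (default) they are selected by
#'   minimizing the UBRE score (see [select_lambda()]).
#' @param ... Passed to [select_lambda()].
#' @return Object of class `gam_fit`: coefficients, per-smooth blocks
#'   (knots, constraint transform, column indices), selected `lambda`,
#'   `edf`, `deviance`, `ubre`, `converged`, `n_obs`, `n_deaths`.
#' @examples
#' sc <- cell_scenario(base_rate = 5)
#' dates <- seq(as.Date("1990-01-01"), as.Date("1993-12-31"), by = "day")
#' tm <- gen_temperature(sc, dates, 1)
#' cov <- gen_covariates(dates, 2)
#' y <- gen_deaths(tm, sc, dates, 3)
#' d <- data.frame(date = dates, tmean = tm, precip = cov$precip,
#'                 pressure = cov$pressure, deaths = y)
#' \donttest{
#' fit <- fit_model(d)
#' extract_mmt(eval_curve(fit))
#' }
#' @export
fit_model <- function(data, spec = c("eq1", "eq1_2dfy", "eq3"),
                      s1_df = 5L, s2_df = 3L, s3_df = 3L,
                      lambda = NULL, ...) {
  spec <- match.arg(spec)
  required <- c("date", "tmean", "precip", "pressure", "deaths")
  if (!all(required %in% names(data)))
    stop("missing covariate column(s): ",
         paste(setdiff(required, names(data)), collapse = ", "))
  data <- data[order(data$date), , drop = FALSE]
  dates <- check_dates(data$date)
  if (is.null(data$hw) || is.null(data$cs)) {
    fl <- label_extremes(data$tmean)
    data$hw <- fl$hw; data$cs <- fl$cs
  }
  if (is.null(data$dow)) data$dow <- day_of_week(dates)

  if (spec == "eq3") {
    if (nrow(data) <= 6L) stop("lagged model needs more than 6 days")
    cum <- cumsum(data$tmean)
    lag6 <- c(rep(NA_real_, 6L), (cum[6:(nrow(data) - 1L)] -
                                    c(0, cum[1:(nrow(data) - 7L)])) / 6)
    data$lag6 <- lag6
    data <- data[-(1:6), , drop = FALSE]
    dates <- dates[-(1:6)]
  }

  n <- nrow(data)
  n_years <- n / 365.25
  dfy <- switch(spec, eq1 = 1, eq1_2dfy = 2, eq3 = 4)
  s4_df <- max(2L, as.integer(round(dfy * n_years)))
  tscaled <- (seq_len(n) - 1) / max(n - 1, 1)

  smooth_defs <- list(list(name = "s1", x = data$tmean, df = s1_df))
  if (spec == "eq3")
    smooth_defs <- c(smooth_defs,
                     list(list(name = "s1b", x = data$lag6, df = s1_df)))
  smooth_defs <- c(smooth_defs, list(
    list(name = "s2", x = data$precip, df = s2_df),
    list(name = "s3", x = data$pressure, df = s3_df),
    list(name = "s4", x = tscaled, df = s4_df)))

  # Parametric block: intercept, Dow contrasts vs Monday, Hw, Cs.
  dow_cols <- vapply(2:7, function(d) as.numeric(data$dow == d),
                     numeric(n))
  colnames(dow_cols) <- paste0("dow", 2:7)
  Xpar <- cbind(intercept = 1, dow_cols, hw = data$hw, cs = data$cs)
  # A period may contain no qualifying heat-wave/cold-spell runs; drop
  # the resulting all-zero dummy columns to keep the design full rank.
  keep_par <- colSums(abs(Xpar)) > 0
  Xpar <- Xpar[, keep_par, drop = FALSE]

  blocks <- list()
  Xs <- list(Xpar)
  penalties <- list()
  col_at <- ncol(Xpar)
  for (sd_ in smooth_defs) {
    knots <- place_knots(sd_$x, sd_$df)
    bas <- crs_basis(sd_$x, knots)
    con <- center_constraint(bas$X, bas$S)
    idx <- col_at + seq_len(ncol(con$X))
    blocks[[sd_$name]] <- list(knots = knots, Z = con$Z, idx = idx,
                               Fmap = bas$F, df = sd_$df)
    Xs[[length(Xs) + 1L]] <- con$X
    penalties[[length(penalties) + 1L]] <- list(idx = idx, S = con$S)
    col_at <- col_at + ncol(con$X)
  }
  X <- do.call(cbind, Xs)

  if (is.null(lambda)) {
    sel <- select_lambda(X, penalties, data$deaths, ...)
    lambda <- sel$lambda
    fit <- sel$fit
  } else {
    fit <- pirls_fit(X, penalties, lambda, data$deaths)
  }

  for (nm in names(blocks))
    blocks[[nm]]$edf <- sum(fit$edf_by_col[blocks[[nm]]$idx])
  structure(list(coefficients = fit$coefficients, blocks = blocks,
                 lambda = lambda, edf = fit$edf, deviance = fit$deviance,
                 ubre = ubre_score(fit), converged = fit$converged,
                 n_obs = fit$n_obs, n_deaths = sum(data$deaths),
                 fitted = fit$fitted, spec = spec,
                 parametric = colnames(Xpar)),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat(sprintf("<gam_fit> %s: n = %d days, %d deaths\n", x$spec, x$n_obs,
              x$n_deaths),
      sprintf("  deviance %.1f, EDF %.1f, UBRE %.4f, converged: %s\n",
              x$deviance, x$edf, x$ubre, x$converged),
      sprintf("  lambda: %s\n",
              paste(signif(x$lambda, 3), collapse = ", ")), sep = "")
  invisible(x)
}

# Evaluate one smooth block of a fitted model at new covariate values.
eval_smooth <- function(fit, name, x) {
  blk <- fit$blocks[[name]]
  if (is.null(blk)) stop("no smooth named ", name)
  rows <- crs_design(x, blk$knots, blk$Fmap)
  drop(rows %*% blk$Z %*% fit$coefficients[blk$idx])
}
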