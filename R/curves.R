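# Curve abstractions: the fitted temperature smooth on a fixed 0.1-degree
# lattice, the minimum mortality temperature, heat-side mortality ratios,
# U/J shape classification and cell eligibility.

#' Temperature grid used for curve evaluation (0 to 30 C by 0.1)
#' @export
curve_grid <- function() seq(0, 30, by = 0.1)

#' Evaluate the fitted temperature-mortality curve
#'
#' Evaluates the temperature smooth of a fitted model at 0.0, 0.1, ...,
#' 30.0 degrees C (301 values), extrapolating linearly beyond the knot
#' range.  For the lagged model the curve is the sum of the same-day and
#' lagged smooths, both evaluated at the same temperature value.
#'
#' @param fit A [fit_model()] result.
#' @return Numeric vector of 301 curve values (log-rate scale, defined up
#'   to a constant) with attribute `converged`.
#' @export
eval_curve <- function(fit) {
  tg <- curve_grid()
  curve <- eval_smooth(fit, "s1", tg)
  if (!is.null(fit$blocks$s1b)) curve <- curve + eval_smooth(fit, "s1b", tg)
  attr(curve, "converged") <- fit$converged
  curve
}

#' Minimum mortality temperature of a curve
#'
#' The temperature (0.1-degree precision) at which the curve attains its
#' minimum on 0-30 C; ties are broken toward the lowest temperature.
#'
#' @param curve 301 finite curve values from [eval_curve()].
#' @return MMT in degrees C.
#' @export
extract_mmt <- function(curve) {
  stopifnot(length(curve) == 301L, all(is.finite(curve)))
  curve_grid()[which.min(curve)]  # which.min returns the first minimum
}

#' Heat-side mortality ratios of a curve
#'
#' `RM25 = exp(s1(25) - s1(MMT))` and `RM25/18 = exp(s1(25) - s1(18))`,
#' read off the 0.1-degree curve lattice.  Both are invariant to adding a
#' constant to the curve.
#'
#' @param curve 301 curve values.
#' @param mmt The minimum mortality temperature (a lattice value).
#' @return Named list with `rm25` and `rm25_18`.
#' @export
rm_ratios <- function(curve, mmt) {
  stopifnot(length(curve) == 301L)
  at <- function(temp) curve[as.integer(round(temp * 10)) + 1L]
  list(rm25 = exp(at(25) - at(mmt)), rm25_18 = exp(at(25) - at(18)))
}

#' Classify the U/J shape of a curve
#'
#' A curve is U/J-shaped when its minimum is interior (between 0.5 and
#' 29.5 C) and both endpoints lie strictly above the minimum (by more
#' than `delta`).  The classification is invariant to vertical shifts and
#' to positive rescaling of the curve.
#'
#' @param curve 301 curve values.
#' @param delta Margin the endpoints must exceed the minimum by
#'   (default 0, strict inequality).
#' @return Logical.
#' @export
classify_uj <- function(curve, delta = 0) {
  stopifnot(length(curve) == 301L, all(is.finite(curve)))
  tg <- curve_grid()
  amin <- tg[which.min(curve)]
  m <- min(curve)
  amin >= 0.5 && amin <= 29.5 && curve[1L] > m + delta &&
    curve[301L] > m + delta
}

#' Cell eligibility by death count
#'
#' A cell enters an analysis when its death count strictly exceeds the
#' threshold (22,500 for a 42-year analysis at about 1.5 deaths/day;
#' 7,500 per 14-year period, with sensitivity thresholds 15,000, 22,500
#' and 37,500).  For by-period analyses a cell must be eligible in every
#' period simultaneously.
#'
#' @param n_deaths Death count (>= 0).
#' @param threshold Eligibility threshold.
#' @return Logical.
#' @export
square_eligibility <- function(n_deaths, threshold) {
  if (any(n_deaths < 0)) stop("negative death count")
  n_deaths > threshold
}

#' Summarise a fitted model as one curve-summary row
#'
#' @param fit A [fit_model()] result.
#' @param cell_id,period_id Identifiers carried into the row.
#' @param threshold Eligibility threshold for this analysis.
#' @return One-row `data.frame` with `cell_id`, `period_id`, `mmt`,
#'   `rm25`, `rm25_18`, `uj_shaped`, `n_deaths`, `eligible`, `converged`;
#'   the full 301-value curve is attached as attribute `curve`.
#' @export
summarize_curve <- function(fit, cell_id = NA_character_,
                            period_id = NA_character_, threshold = 7500) {
  curve <- eval_curve(fit)
  mmt <- extract_mmt(curve)
  rm <- rm_ratios(curve, mmt)
  out <- data.frame(cell_id = cell_id, period_id = period_id, mmt = mmt,
                    rm25 = rm$rm25, rm25_18 = rm$rm25_18,
                    uj_shaped = classify_uj(curve),
                    n_deaths = fit$n_deaths,
                    eligible = square_eligibility(fit$n_deaths, threshold),
                    converged = fit$converged)
  attr(out, "curve") <- curve
  out
}
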