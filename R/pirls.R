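# Penalized iteratively reweighted least squares for the Poisson GAM, the
# UBRE score, and deterministic smoothing-parameter selection by grid
# coordinate descent with golden-section refinement.

poisson_deviance <- function(y, mu) {
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

# Solve M x = b, escalating a relative ridge until the system is
# numerically non-singular (degenerate designs only).
solve_ridged <- function(M, b, scale) {
  out <- tryCatch(solve(M, b), error = function(e) NULL)
  ridge <- 1e-8 * scale
  while (is.null(out) && ridge < scale) {
    out <- tryCatch(solve(M + ridge * diag(nrow(M)), b),
                    error = function(e) NULL)
    ridge <- ridge * 100
  }
  if (is.null(out)) stop("singular working system")
  out
}

#' Fit a penalized Poisson regression by P-IRLS
#'
#' Iterates the standard penalized weighted least squares update for the
#' log link: weights `w = mu`, working response `z = eta + (y - mu)/mu`,
#' solving `(X'WX + sum_j lambda_j S_j) beta = X'Wz`.  Deviance increases
#' trigger step-halving; fitted means are floored at 1e-10 so zero-count
#' days are safe.  Iteration stops when the relative deviance change
#' falls below `tol` (default 1e-8) or after `maxit` iterations.
#'
#' @param X Full design matrix (n x p).
#' @param penalties List of penalty blocks, each a list with `idx`
#'   (column indices into `X`) and `S` (penalty matrix of matching size).
#' @param lambda Non-negative smoothing parameters, one per penalty block.
#' @param y Non-negative integer response.
#' @param beta_init Optional warm-start coefficients.
#' @param tol,maxit Convergence tolerance and iteration cap.
#' @return List of class `pirls_fit` with `coefficients`, `fitted`,
#'   `deviance`, `edf` (trace of the influence matrix), `lambda`,
#'   `converged`, `iter`, `n_obs`.
#' @export
pirls_fit <- function(X, penalties, lambda, y, beta_init = NULL,
                      tol = 1e-8, maxit = 100L) {
  if (any(y < 0)) stop("`y` must be non-negative counts")
  if (length(lambda) != length(penalties))
    stop("one lambda per penalty block required")
  if (any(lambda < 0)) stop("lambdas must be non-negative")
  n <- nrow(X); p <- ncol(X)
  Slam <- matrix(0, p, p)
  for (j in seq_along(penalties)) {
    idx <- penalties[[j]]$idx
    Slam[idx, idx] <- Slam[idx, idx] + lambda[j] * penalties[[j]]$S
  }
  pen <- function(b) drop(crossprod(b, Slam %*% b))
  objective <- function(y, mu, b) poisson_deviance(y, mu) + pen(b)

  if (is.null(beta_init)) {
    mu <- pmax(y + 0.1, 1e-10)
    eta <- log(mu)
    beta <- NULL
    obj <- Inf
  } else {
    beta <- beta_init
    eta <- drop(X %*% beta)
    mu <- pmax(exp(eta), 1e-10)
    obj <- objective(y, mu, beta)
  }

  converged <- FALSE
  iter <- 0L
  A <- NULL
  repeat {
    iter <- iter + 1L
    w <- mu
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    A <- crossprod(X * sw)
    b <- crossprod(X, w * z)
    beta_new <- solve_ridged(A + Slam, b, mean(diag(A)))
    beta_new <- drop(beta_new)
    eta_new <- drop(X %*% beta_new)
    mu_new <- pmax(exp(eta_new), 1e-10)
    obj_new <- objective(y, mu_new, beta_new)
    # Step-halve toward the previous coefficients if the penalized
    # deviance increased (only possible once beta exists).
    if (!is.null(beta) && is.finite(obj)) {
      half <- 0L
      while ((!is.finite(obj_new) || obj_new > obj + 1e-10) && half < 30L) {
        beta_new <- (beta_new + beta) / 2
        eta_new <- drop(X %*% beta_new)
        mu_new <- pmax(exp(eta_new), 1e-10)
        obj_new <- objective(y, mu_new, beta_new)
        half <- half + 1L
      }
    }
    done <- is.finite(obj) && abs(obj - obj_new) < tol * (abs(obj_new) + 0.1)
    beta <- beta_new; eta <- eta_new; mu <- mu_new; obj <- obj_new
    if (done) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  # Influence trace at the final weights: tr[(X'WX + S)^{-1} X'WX].
  A <- crossprod(X * sqrt(mu))
  edf_by_col <- diag(solve_ridged(A + Slam, A, mean(diag(A))))
  structure(list(coefficients = beta, fitted = mu,
                 deviance = poisson_deviance(y, mu),
                 edf = sum(edf_by_col), edf_by_col = edf_by_col,
                 lambda = lambda, converged = converged, iter = iter,
                 n_obs = n),
            class = "pirls_fit")
}

#' Unbiased risk estimator score
#'
#' `UBRE = D/n - phi + 2 phi EDF / n` for a fit with deviance `D`,
#' `n` observations and effective degrees of freedom `EDF`; the scale
#' `phi` is 1 for the Poisson family.
#'
#' @param fit A [pirls_fit()] result (or any list with `deviance`, `edf`,
#'   `n_obs`).
#' @param phi Scale parameter (default 1).
#' @return The UBRE score (scalar).
#' @export
ubre_score <- function(fit, phi = 1) {
  if (fit$n_obs == 0) stop("no observations")
  fit$deviance / fit$n_obs - phi + 2 * phi * fit$edf / fit$n_obs
}

#' Select smoothing parameters by minimizing the UBRE score
#'
#' Deterministic search: coordinate descent of `log10 lambda_j` over the
#' integer grid -6..6, cycling over smooths until no coordinate changes
#' (at most `max_cycles` cycles), followed by one golden-section
#' refinement per coordinate on the interval bracketing the grid optimum.
#'
#' @inheritParams pirls_fit
#' @param grid Candidate `log10 lambda` values (default -6..6).
#' @param max_cycles Maximum coordinate-descent cycles (default 5).
#' @param refine_iter Golden-section iterations per coordinate.
#' @return List with `lambda` (selected vector), `fit` (the [pirls_fit()]
#'   at the optimum) and `ubre`.
#' @export
select_lambda <- function(X, penalties, y, grid = -6:6, max_cycles = 5L,
                          refine_iter = 10L) {
  m <- length(penalties)
  if (m < 1L) stop("at least one smooth required")
  ws <- new.env(parent = emptyenv())  # warm start + memo cache
  ws$beta <- NULL
  ws$memo <- list()
  score_at <- function(loglam) {
    key <- paste(sprintf("%.6f", loglam), collapse = ",")
    hit <- ws$memo[[key]]
    if (!is.null(hit)) return(hit)
    fit <- pirls_fit(X, penalties, 10^loglam, y, beta_init = ws$beta)
    if (fit$converged) ws$beta <- fit$coefficients
    s <- ubre_score(fit)
    ws$memo[[key]] <- s
    s
  }
  loglam <- rep(0, m)
  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    for (j in seq_len(m)) {
      scores <- vapply(grid, function(g) {
        ll <- loglam; ll[j] <- g; score_at(ll)
      }, numeric(1))
      best <- grid[which.min(scores)]
      if (best != loglam[j]) { loglam[j] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  # Golden-section refinement on [best - 1, best + 1] per coordinate.
  gr <- (sqrt(5) - 1) / 2
  for (j in seq_len(m)) {
    lo <- loglam[j] - 1; hi <- loglam[j] + 1
    a <- hi - gr * (hi - lo); b <- lo + gr * (hi - lo)
    fa <- { ll <- loglam; ll[j] <- a; score_at(ll) }
    fb <- { ll <- loglam; ll[j] <- b; score_at(ll) }
    for (it in seq_len(refine_iter)) {
      if (fa < fb) {
        hi <- b; b <- a; fb <- fa
        a <- hi - gr * (hi - lo)
        fa <- { ll <- loglam; ll[j] <- a; score_at(ll) }
      } else {
        lo <- a; a <- b; fa <- fb
        b <- lo + gr * (hi - lo)
        fb <- { ll <- loglam; ll[j] <- b; score_at(ll) }
      }
    }
    cand <- if (fa < fb) a else b
    if (score_at({ ll <- loglam; ll[j] <- cand; ll }) <
        score_at(loglam)) loglam[j] <- cand
  }
  fit <- pirls_fit(X, penalties, 10^loglam, y, beta_init = ws$beta)
  list(lambda = 10^loglam, fit = fit, ubre = ubre_score(fit))
}
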