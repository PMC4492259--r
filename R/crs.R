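# Cubic regression spline basis parameterized by function values at the
# knots, with the natural-spline wiggliness penalty (integrated squared
# second derivative).  Outside the knot range the spline continues
# linearly.  This is the classical value-at-knots parameterization: the
# j-th basis function is 1 at knot j and 0 at every other knot.

#' Place spline knots at distribution quantiles
#'
#' A smooth with `df` degrees of freedom gets `df + 1` knots at the
#' empirical quantiles `j/df`, `j = 0..df` (minimum and maximum included),
#' using the linear-interpolation quantile definition.  Duplicate
#' quantiles (common for zero-inflated covariates such as precipitation)
#' are perturbed minimally to restore strict monotonicity.
#'
#' @param x Covariate values.
#' @param df Target degrees of freedom (integer >= 2).
#' @return Strictly increasing numeric vector of `df + 1` knots.
#' @export
place_knots <- function(x, df) {
  df <- as.integer(df)
  if (df < 2L) stop("`df` must be >= 2")
  if (length(unique(x)) < df + 1L)
    stop("fewer distinct covariate values than knots")
  k <- stats::quantile(x, probs = seq(0, 1, length.out = df + 1L),
                       names = FALSE, type = 7)
  if (any(diff(k) <= 0)) {
    # spread duplicated quantiles (zero-inflated covariates) far enough
    # apart that the basis stays well conditioned
    eps <- max(1e-3 * diff(range(x)), 1e-8)
    for (i in seq_along(k)[-1L])
      if (k[i] <= k[i - 1L] + eps / 2) k[i] <- k[i - 1L] + eps
  }
  k
}

#' Cubic regression spline basis and penalty
#'
#' Builds the `n x k` evaluation matrix of the natural cubic spline
#' interpolant parameterized by its values at `k` knots, together with the
#' `k x k` penalty matrix whose quadratic form is the integral of the
#' squared second derivative.  The penalty is positive semi-definite with
#' nullspace spanned by constant and linear functions of the knots.
#' Evaluation outside the knot range extrapolates linearly.
#'
#' @param x Values at which to evaluate the basis.
#' @param knots Strictly increasing knot vector (length >= 3).
#' @return List with `X` (n x k basis), `S` (k x k penalty), `knots`, and
#'   the internal curvature map `F` reused for prediction.
#' @export
crs_basis <- function(x, knots) {
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  k <- length(knots)
  if (k < 3L) stop("at least 3 knots required")
  h <- diff(knots)
  # D maps knot values to second differences, B the tridiagonal Gram
  # matrix; F = B^{-1} D gives second derivatives at interior knots.
  D <- matrix(0, k - 2L, k)
  B <- matrix(0, k - 2L, k - 2L)
  for (i in seq_len(k - 2L)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1L] <- -1 / h[i] - 1 / h[i + 1L]
    D[i, i + 2L] <- 1 / h[i + 1L]
    B[i, i] <- (h[i] + h[i + 1L]) / 3
    if (i < k - 2L) B[i, i + 1L] <- B[i + 1L, i] <- h[i + 1L] / 6
  }
  Fmap <- rbind(0, solve(B, D), 0)  # natural: zero curvature at ends
  S <- t(D) %*% solve(B, D)
  S <- (S + t(S)) / 2
  list(X = crs_design(x, knots, Fmap), S = S, knots = knots, F = Fmap)
}

# Evaluate the basis rows at arbitrary x given knots and curvature map.
crs_design <- function(x, knots, Fmap) {
  k <- length(knots)
  n <- length(x)
  h <- diff(knots)
  X <- matrix(0, n, k)
  j <- pmin(pmax(findInterval(x, knots), 1L), k - 1L)
  inside <- x >= knots[1L] & x <= knots[k]
  if (any(inside)) {
    xi <- x[inside]; ji <- j[inside]; hi <- h[ji]
    am <- (knots[ji + 1L] - xi) / hi
    ap <- (xi - knots[ji]) / hi
    cm <- ((knots[ji + 1L] - xi)^3 / hi - hi * (knots[ji + 1L] - xi)) / 6
    cp <- ((xi - knots[ji])^3 / hi - hi * (xi - knots[ji])) / 6
    Xi <- matrix(0, length(xi), k)
    Xi[cbind(seq_along(xi), ji)] <- am
    Xi[cbind(seq_along(xi), ji + 1L)] <- Xi[cbind(seq_along(xi), ji + 1L)] + ap
    Xi <- Xi + cm * Fmap[ji, , drop = FALSE] + cp * Fmap[ji + 1L, , drop = FALSE]
    X[inside, ] <- Xi
  }
  left <- x < knots[1L]
  if (any(left)) {
    # f(x) = f(K1) + (x - K1) f'(K1); f'(K1) = (b2 - b1)/h1 - h1/6 * F[2,]b
    slope_row <- -Fmap[2L, ] * h[1L] / 6
    slope_row[1L] <- slope_row[1L] - 1 / h[1L]
    slope_row[2L] <- slope_row[2L] + 1 / h[1L]
    base <- matrix(0, sum(left), k); base[, 1L] <- 1
    X[left, ] <- base + (x[left] - knots[1L]) %o% slope_row
  }
  right <- x > knots[k]
  if (any(right)) {
    slope_row <- Fmap[k - 1L, ] * h[k - 1L] / 6
    slope_row[k - 1L] <- slope_row[k - 1L] - 1 / h[k - 1L]
    slope_row[k] <- slope_row[k] + 1 / h[k - 1L]
    base <- matrix(0, sum(right), k); base[, k] <- 1
    X[right, ] <- base + (x[right] - knots[k]) %o% slope_row
  }
  X
}

#' Absorb the sum-to-zero identifiability constraint
#'
#' Additive smooths are only identifiable up to a constant; each smooth is
#' constrained to sum to zero over the fitting data.  The constraint is
#' absorbed by reparameterizing with an orthonormal null-space basis `Z`
#' of the column-sum vector, giving `k - 1` constrained columns whose
#' column sums vanish.  `Z` also back-transforms constrained coefficients
#' to full values-at-knots coefficients.
#'
#' @param X Unconstrained basis block (n x k).
#' @param S Matching penalty (k x k).
#' @return List with `X` (n x k-1), `S` (k-1 x k-1) and `Z` (k x k-1).
#' @export
center_constraint <- function(X, S) {
  C <- colSums(X)
  if (sqrt(sum(C^2)) < 1e-12) stop("degenerate (all-zero column sums) block")
  qrC <- qr(matrix(C, ncol = 1L))
  Z <- qr.Q(qrC, complete = TRUE)[, -1L, drop = FALSE]
  list(X = X %*% Z, S = crossprod(Z, S %*% Z), Z = Z)
}
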