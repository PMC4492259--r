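# Spatial structure: inverse-squared-distance interpolation of cell-level
# values and Moran's index with the same weights.

#' Inverse-squared-distance interpolation at one point
#'
#' The interpolated value at `z` is the weighted mean of the field values
#' with weights `w_i = |c_i - z|^-2` (inverse squared Euclidean distance
#' in degree coordinates).  When `z` coincides with a centre (distance
#' below 1e-12) the centre's value is returned exactly -- the limit of the
#' formula.
#'
#' @param centers Two-column matrix (lon, lat) of value locations.
#' @param values Numeric values at the centres.
#' @param z Length-2 coordinate of the query point.
#' @return Interpolated scalar.
#' @export
idw_interpolate <- function(centers, values, z) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 1L) stop("empty field")
  stopifnot(nrow(centers) == length(values))
  d2 <- (centers[, 1L] - z[1L])^2 + (centers[, 2L] - z[2L])^2
  hit <- which(d2 < 1e-24)  # squared distance: (1e-12)^2
  if (length(hit)) return(values[hit[1L]])
  w <- 1 / d2
  sum(w * values) / sum(w)
}

#' Interpolate a whole surface
#'
#' Applies [idw_interpolate()] at every query point.  Being a convex
#' combination, the surface is bounded by the range of the input values.
#'
#' @param centers,values As in [idw_interpolate()].
#' @param query Two-column matrix of query coordinates.
#' @return `data.frame` with columns `lon`, `lat`, `value`.
#' @export
interpolate_surface <- function(centers, values, query) {
  query <- as.matrix(query)
  if (nrow(query) < 1L) stop("empty query grid")
  v <- vapply(seq_len(nrow(query)), function(i)
    idw_interpolate(centers, values, query[i, ]), numeric(1))
  data.frame(lon = query[, 1L], lat = query[, 2L], value = v)
}

#' Moran's index with inverse-squared-distance weights
#'
#' Global spatial autocorrelation of a field observed at distinct
#' locations, with weights `w_ij = |c_i - c_j|^-2` (the same weights as
#' the interpolation).  Returns the index, its expectation `-1/(n-1)`,
#' the variance under the normality assumption, the normal z-score and
#' two-sided p-value, and optionally a permutation p-value.
#'
#' @param centers Two-column coordinate matrix (n >= 4 locations).
#' @param x Field values.
#' @param n_perm If > 0, also compute a two-sided permutation p-value
#'   from `n_perm` random permutations (seeded, reproducible).
#' @param perm_seed Seed for the permutation null.
#' @param row_standardize Divide each row of the weight matrix by its
#'   sum before computing the index (default `FALSE`: raw
#'   inverse-squared-distance weights).
#' @return List with `I`, `expected`, `variance`, `z`, `p` and, when
#'   requested, `p_perm` and the vector `perm` of null draws.
#' @export
morans_i <- function(centers, x, n_perm = 0L, perm_seed = 1L,
                     row_standardize = FALSE) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n < 4L) stop("need at least 4 locations")
  stopifnot(length(x) == n)
  d2 <- as.matrix(stats::dist(centers))^2
  if (any(d2[upper.tri(d2)] == 0)) stop("centers must be distinct")
  W <- 1 / d2
  diag(W) <- 0
  if (row_standardize) W <- W / rowSums(W)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("field has zero variance")
  S0 <- sum(W)
  I_of <- function(v) {
    vc <- v - mean(v)
    (n / S0) * drop(vc %*% W %*% vc) / sum(vc^2)
  }
  I <- I_of(x)
  E <- -1 / (n - 1)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  V <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - E^2
  z <- (I - E) / sqrt(V)
  p <- 2 * stats::pnorm(-abs(z))
  out <- list(I = I, expected = E, variance = V, z = z, p = p)
  if (n_perm > 0L) {
    perm <- with_seed(perm_seed,
                      vapply(seq_len(n_perm), function(i) I_of(sample(x)),
                             numeric(1)))
    # two-sided rank p with the observed value counted in the null
    r <- (1 + sum(abs(perm - E) >= abs(I - E))) / (n_perm + 1)
    out$p_perm <- r
    out$perm <- perm
  }
  out
}
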