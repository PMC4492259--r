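# Inverse-squared-distance interpolation and Moran's index.

test_that("interpolation is exact at nodes and normalizes constants", {
  ctr <- lattice_centers(3, 3)
  vals <- rnorm(9)
  for (i in c(1, 5, 9))
    expect_identical(idw_interpolate(ctr, vals, ctr[i, ]), vals[i])
  expect_equal(idw_interpolate(ctr, rep(4.2, 9), c(0.9, 1.1)), 4.2)
  expect_error(idw_interpolate(ctr[0, , drop = FALSE], numeric(0), c(0, 0)),
               "empty")
})

test_that("three-centre interpolation matches hand arithmetic", {
  ctr <- rbind(c(0, 0), c(1, 0), c(0, 1))
  vals <- c(10, 20, 40)
  z <- c(0.5, 0.5)
  d2 <- c(0.5, 0.5, 0.5)
  w <- 1 / d2
  expect_equal(idw_interpolate(ctr, vals, z), sum(w * vals) / sum(w),
               tolerance = 1e-12)
  z2 <- c(0.25, 0)
  d2b <- c(0.0625, 0.5625, 0.0625 + 1)
  expect_equal(idw_interpolate(ctr, vals, z2),
               sum(vals / d2b) / sum(1 / d2b), tolerance = 1e-12)
})

test_that("surfaces are convex combinations and reduce to the scalar op", {
  ctr <- lattice_centers(4, 4)
  vals <- runif(16, 5, 25)
  q <- as.matrix(expand.grid(seq(0.3, 2.2, 0.37), seq(0.3, 2.2, 0.37)))
  surf <- interpolate_surface(ctr, vals, q)
  expect_true(all(surf$value >= min(vals) & surf$value <= max(vals)))
  expect_equal(surf$value[3], idw_interpolate(ctr, vals, q[3, ]))
  one <- interpolate_surface(ctr[1, , drop = FALSE], vals[1], q)
  expect_equal(one$value, rep(vals[1], nrow(q)), tolerance = 1e-12)
})

test_that("Moran's I matches a brute-force double loop and ape", {
  set.seed(12)
  for (n in c(8, 16, 30)) {
    ctr <- cbind(runif(n), runif(n))
    x <- rnorm(n)
    got <- morans_i(ctr, x)
    # brute force
    W <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) if (i != j)
      W[i, j] <- 1 / sum((ctr[i, ] - ctr[j, ])^2)
    xc <- x - mean(x)
    num <- 0
    for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * xc[i] * xc[j]
    I_bf <- n / sum(W) * num / sum(xc^2)
    expect_equal(got$I, I_bf, tolerance = 1e-12)
    expect_equal(got$expected, -1 / (n - 1))
    # normality-assumption variance recomputed from explicitly looped
    # S0, S1, S2
    S0 <- sum(W)
    S1 <- 0
    for (i in 1:n) for (j in 1:n) S1 <- S1 + (W[i, j] + W[j, i])^2
    S1 <- S1 / 2
    S2 <- sum(sapply(1:n, function(i) (sum(W[i, ]) + sum(W[, i]))^2))
    E <- -1 / (n - 1)
    V_bf <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - E^2
    expect_equal(got$variance, V_bf, tolerance = 1e-12)
    skip_if_not_installed("ape")
    # ape row-standardizes the supplied weight matrix internally and
    # reports the randomization-test sd, so only I and E are comparable
    got_rs <- morans_i(ctr, x, row_standardize = TRUE)
    ref <- ape::Moran.I(x, W)
    expect_equal(got_rs$I, ref$observed, tolerance = 1e-10)
    expect_equal(got_rs$expected, ref$expected, tolerance = 1e-12)
  }
})

test_that("a lattice row gradient is detected as positive autocorrelation", {
  ctr <- lattice_centers(4, 4)
  x <- rep(1:4, each = 4) + 0.01 * rnorm(16)  # row index + jitter
  set.seed(1)
  got <- morans_i(ctr, x, n_perm = 999, perm_seed = 3)
  expect_gt(got$I, 0)
  expect_lt(got$p, 0.05)
  expect_lt(got$p_perm, 0.05)
  # permutation null centres on -1/(n-1)
  se <- sd(got$perm) / sqrt(length(got$perm))
  expect_lt(abs(mean(got$perm) - (-1 / 15)), 3 * se + 0.02)
})

test_that("Moran's I is affine invariant and rejects degenerate fields", {
  ctr <- lattice_centers(3, 3)
  x <- rnorm(9)
  base <- morans_i(ctr, x)$I
  expect_equal(morans_i(ctr, 3 * x - 7)$I, base, tolerance = 1e-12)
  expect_equal(morans_i(ctr, -2 * x + 1)$I, base, tolerance = 1e-12)
  expect_error(morans_i(ctr, rep(1, 9)), "variance")
  expect_error(morans_i(ctr[1:3, ], rnorm(3)), "at least 4")
})

test_that("normal and permutation tests usually agree on strong signal", {
  set.seed(13)
  agree <- 0
  n_fields <- 20
  ctr <- lattice_centers(4, 4)
  for (r in seq_len(n_fields)) {
    x <- rep(1:4, each = 4) + 0.4 * rnorm(16)
    got <- morans_i(ctr, x, n_perm = 499, perm_seed = r)
    agree <- agree + ((got$p < 0.05) == (got$p_perm < 0.05))
  }
  expect_gte(agree / n_fields, 0.9)
})
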