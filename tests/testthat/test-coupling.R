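# Coupling statistics: pooled absolute correlation, canonical correlation,
# region averaging, and the stat-matrix assembly.

test_that("pooled absolute correlation obeys its identities and null scale", {
  x <- matrix(rnorm(10 * 50), 10)
  expect_equal(abs_correlation(x, x), 1)
  expect_equal(abs_correlation(x, -x), 1)
  expect_error(abs_correlation(x, matrix(0, 10, 50)), "flat")
  expect_error(abs_correlation(x, x[, 1:10]), "same shape")

  # independent inputs: spread of the statistic ~ 1/sqrt(L*T)
  L <- 20; Tn <- 50
  vals <- withr::with_seed(5, replicate(300, {
    abs_correlation(matrix(rnorm(L * Tn), L), matrix(rnorm(L * Tn), L))
  }))
  expect_lt(abs(sqrt(mean(vals^2)) - 1 / sqrt(L * Tn)), 0.3 / sqrt(L * Tn))
})

test_that("canonical correlation reduces to correlation for single channels", {
  withr::with_seed(7, {
    x <- rnorm(400); y <- 0.5 * x + rnorm(400)
    expect_equal(canonical_correlation(x, y), abs_correlation(x, y),
                 tolerance = 1e-12)
  })
})

test_that("canonical correlation is 1 for linearly mixed groups and matches the optimization oracle", {
  withr::with_seed(8, {
    X <- matrix(rnorm(3 * 600), 3)
    M <- matrix(rnorm(9), 3)  # invertible mixing w.p. 1
    expect_equal(canonical_correlation(X, M %*% X), 1, tolerance = 1e-8)

    # independent groups of 2-3 channels vs direct maximization of
    # corr(a'x, b'y): agreement to 1e-6
    for (s in 1:6) {
      n <- sample(2:3, 1); m <- sample(2:3, 1)
      X <- matrix(rnorm(n * 500), n)
      Y <- matrix(rnorm(m * 500), m)
      Y[1, ] <- Y[1, ] + 0.2 * X[1, ]   # some genuine coupling
      expect_equal(canonical_correlation(X, Y), oracle_canoncorr(X, Y),
                   tolerance = 1e-6)
    }
  })
})

test_that("canonical correlation is invariant to within-group recombination", {
  withr::with_seed(9, {
    X <- matrix(rnorm(3 * 500), 3)
    Y <- matrix(rnorm(3 * 500), 3)
    Y[2, ] <- Y[2, ] - 0.3 * X[3, ]
    ref <- canonical_correlation(X, Y)
    for (k in 1:5) {
      A <- matrix(rnorm(9), 3)
      B <- diag(sample(c(-1, 1), 3, replace = TRUE))  # sign flips included
      expect_equal(canonical_correlation(A %*% X, B %*% Y), ref,
                   tolerance = 1e-8)
    }
  })
})

test_that("canonical correlation guards against degenerate inputs", {
  X <- matrix(rnorm(3 * 500), 3)
  expect_error(canonical_correlation(matrix(rnorm(12), 4, 3), X[, 1:3]),
               "degenerate")
  Xd <- rbind(X, X[1, ] + X[2, ])  # rank-deficient group
  expect_warning(canonical_correlation(Xd, matrix(rnorm(2 * 500), 2)),
                 "rank-deficient")
})

test_that("region averaging coincides with correlation for singleton groups and cancels by design", {
  withr::with_seed(10, {
    x <- rnorm(300); y <- 0.4 * x + rnorm(300)
    expect_equal(region_average_correlation(x, y), abs_correlation(x, y))
    X <- matrix(rnorm(2 * 300), 2)
    expect_equal(region_average_correlation(X, X), 1)
    # exact cancellation: +s and -s average to zero
    s <- rnorm(300)
    expect_error(region_average_correlation(rbind(s, -s), X), "cancellation")
  })
})

test_that("stat matrices are symmetric, bounded, and counted correctly", {
  region_of <- rep(1:3, each = 3)
  ep <- make_iid_epochs(E = 2, Tn = 40, N = 9, L = 10, seed = 11,
                        region_of = region_of)

  s <- compute_stat_matrix(ep, "sensor")
  expect_equal(nrow(s$pairs), 36)      # 9*8/2 off-diagonal pairs
  expect_true(all(is.na(diag(s$stat[1, , ]))))
  expect_equal(s$stat[1, , ], t(s$stat[1, , ]))
  expect_true(all(s$stat >= 0 & s$stat <= 1, na.rm = TRUE))

  r <- compute_stat_matrix(ep, "region")
  expect_equal(nrow(r$pairs), 3)
  expect_true(all(r$stat >= 0 & r$stat <= 1, na.rm = TRUE))

  a <- compute_stat_matrix(ep, "region", measure = "average")
  expect_true(all(a$stat >= 0 & a$stat <= 1, na.rm = TRUE))

  expect_error(compute_stat_matrix(ep, "sensor", measure = "canonical"),
               "sensor mode")
  ep$region_of <- NULL
  expect_error(compute_stat_matrix(ep, "region"), "region map")
})

test_that("the Gram-matrix fast path agrees with the exposed per-pair operations", {
  region_of <- c(1, 1, 2, 2, 3, 3)
  ep <- make_iid_epochs(E = 1, Tn = 30, N = 6, L = 8, seed = 12,
                        region_of = region_of)
  # assemble raw group matrices: appended trials, time-major within trial
  rowmat <- function(nn) as.vector(ep$data[1, , nn, ])
  S <- compute_stat_matrix(ep, "sensor")
  expect_equal(S$stat[1, 2, 5],
               abs_correlation(rowmat(2), rowmat(5)), tolerance = 1e-12)

  R <- compute_stat_matrix(ep, "region")
  X1 <- rbind(rowmat(1), rowmat(2))
  X2 <- rbind(rowmat(3), rowmat(4))
  expect_equal(R$stat[1, 1, 2], canonical_correlation(X1, X2),
               tolerance = 1e-9)

  A <- compute_stat_matrix(ep, "region", measure = "average")
  expect_equal(A$stat[1, 1, 2], region_average_correlation(X1, X2),
               tolerance = 1e-12)
})

test_that("stat tables export in long format", {
  ep <- make_iid_epochs(E = 2, Tn = 30, N = 4, L = 5, seed = 13)
  s <- compute_stat_matrix(ep, "sensor")
  df <- as.data.frame(s)
  expect_equal(nrow(df), 2 * 6)
  expect_named(df, c("epoch_label", "node_i", "node_j", "statistic"))
  expect_equal(df$statistic[df$epoch_label == "before"],
               s$stat[cbind(1, s$pairs[, 1], s$pairs[, 2])])
})
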