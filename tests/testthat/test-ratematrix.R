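test_that("uniform parameters give the fully symmetric neighbor matrix", {
  m <- codonRateMatrix(srAssignment(), rho = 1, normalize = FALSE)
  off <- m@Q; diag(off) <- 0
  expect_identical(sort(unique(round(off[off > 0], 12))), 0.25)
  expect_lt(max(abs(rowSums(m@Q))), 1e-12)
  # multi-step pairs have zero rate
  expect_identical(m@Q["AAA", "CCC"], 0)
  expect_identical(m@Q["AAA", "AGG"], 0)
})

test_that("invalid parameters are rejected", {
  expect_error(codonRateMatrix(srAssignment(), rho = -0.1), "non-negative")
  th <- defaultTheta(); th["C:G"] <- -1
  expect_error(codonRateMatrix(srAssignment(), 1, theta = th), "non-negative")
  badPi <- defaultPi(); badPi[1, ] <- c(0.9, 0.2, 0.2, 0.2)
  expect_error(codonRateMatrix(srAssignment(), 1, pi = badPi), "sum to 1")
  expect_error(codonRateMatrix(randomAssignment(3, 1), rho = c(1, 2)),
               "one value per class")
})

test_that("detailed balance and the product-form stationary law hold", {
  for (s in 1:5) {
    prm <- randomModelParams(K = 4, seed = s)
    m <- codonRateMatrix(randomAssignment(4, seed = s), prm$rho, prm$theta, prm$pi)
    p <- stationary(m)
    flux <- p * m@Q
    expect_lt(max(abs(flux - t(flux))), 1e-10)  # detailed balance
    # stationary matches the numerically solved left null vector
    ns <- eigen(t(m@Q))
    v <- Re(ns$vectors[, which.min(abs(ns$values))])
    v <- v / sum(v)
    expect_lt(max(abs(v - p)), 1e-10)
    # reversible symmetrization D^{1/2} Q D^{-1/2} is symmetric
    S <- sqrt(p) * m@Q * rep(1 / sqrt(p), each = 61)
    expect_lt(max(abs(S - t(S))), 1e-10)
    # normalized stationary mean rate is 1
    expect_lt(abs(sum(p * -diag(m@Q)) - 1), 1e-12)
  }
})

test_that("uniform frequencies give the uniform stationary law", {
  p <- stationaryDistribution(defaultPi())
  expect_equal(unname(p), rep(1 / 61, 61), tolerance = 1e-12)
  prm <- randomModelParams(seed = 9)
  expect_equal(sum(stationaryDistribution(prm$pi)), 1, tolerance = 1e-12)
})

test_that("equal class rates collapse any assignment to the SR matrix", {
  prm <- randomModelParams(seed = 2)
  mSR <- codonRateMatrix(srAssignment(), 0.7, prm$theta, prm$pi)
  mK <- codonRateMatrix(randomAssignment(6, seed = 8), rep(0.7, 6),
                        prm$theta, prm$pi)
  expect_equal(mK@Q, mSR@Q, tolerance = 1e-12)
})

test_that("transition matrices are stochastic, ergodic and consistent with expm", {
  prm <- randomModelParams(seed = 4)
  m <- codonRateMatrix(randomAssignment(3, seed = 4), prm$rho[1:3],
                       prm$theta, prm$pi)
  expect_error(transitionMatrix(m, -0.1), "non-negative")
  expect_equal(transitionMatrix(m, 0), diag(61), ignore_attr = TRUE,
               tolerance = 1e-12)
  P <- transitionMatrix(m, 0.7)
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # independent matrix-exponential oracle
  E <- as.matrix(Matrix::expm(m@Q * 0.7))
  expect_lt(max(abs(P - E)), 1e-9)
  # Chapman-Kolmogorov
  expect_lt(max(abs(transitionMatrix(m, 0.3) %*% transitionMatrix(m, 0.45) -
                      transitionMatrix(m, 0.75))), 1e-8)
  # ergodic limit: rows approach the stationary distribution
  Pinf <- transitionMatrix(m, 200)
  expect_lt(max(abs(sweep(Pinf, 2, stationary(m)))), 1e-6)
})
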