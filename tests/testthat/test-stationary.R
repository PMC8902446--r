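test_that("stationary covariance solves the Lyapunov equation exactly in closed-form cases", {
  p <- partition(1, 1, 1, 1)
  # uncoupled: Sigma* = Gamma
  d <- stationary_density(make_system(-diag(4), gamma = 0.01, partition = p))
  expect_equal(d$Sigma, diag(0.01, 4), tolerance = 1e-14)
  expect_equal(d$H, diag(100, 4), tolerance = 1e-10)

  # symmetric drift: equilibrium, Sigma* = -J^-1 Gamma, Q = 0
  J <- diag(c(-2, -1))
  d2 <- stationary_density(make_system(J, gamma = 0.01,
                                       partition = partition(1, 1, 0, 0)))
  expect_equal(d2$Sigma, diag(c(0.005, 0.01)), tolerance = 1e-14)
  expect_lt(frob(d2$Q), 1e-15)

  # antisymmetric coupling: Sigma* = sigma^2 I and Q = sigma^2 C exactly
  C <- matrix(c(0, -0.2, 0.2, 0), 2, 2)
  d3 <- stationary_density(make_system(-diag(2) + C, gamma = 0.01,
                                       partition = partition(1, 1, 0, 0)))
  expect_equal(d3$Sigma, diag(0.01, 2), tolerance = 1e-14)
  expect_equal(d3$Q, 0.01 * C, tolerance = 1e-14)
})

test_that("NESS residuals hold across random stable systems up to n = 12", {
  for (seed in 1:25) {
    n <- 4 + (seed %% 9)
    sys <- random_stable_system(n, seed, homogeneous = seed %% 2 == 0)
    d <- stationary_density(sys)
    gnorm <- max(1, sqrt(sum(sys$gamma^2)))
    expect_lt(d$residuals$lyapunov, 1e-10 * gnorm)
    expect_lt(d$residuals$antisymmetry, 1e-10)
    expect_lt(d$residuals$reconstruction, 1e-8)
    expect_gt(min(eigen(d$Sigma, symmetric = TRUE)$values), 0)
  }
})

test_that("solver agrees with the brute-force Kronecker solve for n <= 6", {
  for (seed in 1:10) {
    sys <- random_stable_system(3 + (seed %% 4), seed)
    d <- stationary_density(sys)
    oracle <- lyap_kron(sys$J, -2 * diag(sys$gamma, sys$partition$n))
    expect_lt(frob(d$Sigma - (oracle + t(oracle)) / 2), 1e-10)
  }
})

test_that("solenoidal matrix matches its own Lyapunov characterization", {
  # Q solves J Q + Q J' = Gamma J' - J Gamma; cross-check against Q = J Sigma + Gamma
  sys <- chain_system()
  G <- diag(sys$gamma, 6)
  Q <- solve_solenoidal(sys)
  oracle <- lyap_kron(sys$J, G %*% t(sys$J) - sys$J %*% G)
  expect_lt(frob(Q - oracle), 1e-12)
  expect_lt(frob(Q + t(Q)), 1e-10)
  expect_identical(solve_solenoidal(sys, q_sign = "negative"), -Q)
})

test_that("degenerate noise is refused rather than pseudo-inverted", {
  sys <- generate_random_system("canonical", p2112, epsilon = 0.1,
                                sigma = 0, seed = 2)
  expect_error(stationary_density(sys), class = "fep_degenerate_error")
})

test_that("covariance series reproduces the printed low-order truncations", {
  sys <- canonical_system(seed = 4)
  C <- sys$C
  G <- diag(0.01, 6)
  expect_equal(covariance_series(C, G, 0)$value, G)
  expect_equal(covariance_series(C, G, 1)$value,
               G + (C %*% G + G %*% t(C)) / 2, tolerance = 1e-15)
  expect_equal(covariance_series(C, G, 2)$value,
               G + (C %*% G + G %*% t(C)) / 2 +
                 (C %*% C %*% G + 2 * C %*% G %*% t(C) + G %*% t(C) %*% t(C)) / 4,
               tolerance = 1e-15)
})

test_that("hessian series matches closed forms and its exactness cases", {
  p <- partition(1, 1, 0, 0)
  expect_equal(hessian_series(matrix(0, 2, 2), 0.1, 2)$value, diag(100, 2))
  # 2x2 skew C: C'C = CC', so the order-2 Hessian is sigma^-2 I — and exact
  C <- matrix(c(0, -0.2, 0.2, 0), 2, 2)
  expect_equal(hessian_series(C, 0.1, 2)$value, diag(100, 2), tolerance = 1e-12)
  d <- stationary_density(make_system(-diag(2) + C, gamma = 0.01, partition = p))
  expect_equal(hessian_series(C, 0.1, 2)$value, d$H, tolerance = 1e-9)
  expect_error(hessian_series(C, c(0.1, 0.2), 2),
               class = "fep_unsupported_mode_error")
})

test_that("solenoidal series is antisymmetric and exact for skew couplings", {
  # symmetric C: zero at order 1 (equilibrium at leading order)
  Cs <- matrix(c(0.1, 0.05, 0.05, -0.1), 2, 2)
  expect_equal(solenoidal_series(Cs, 0.01, 1)$value, matrix(0, 2, 2))
  # skew C: series equals sigma^2 C exactly (C^2 symmetric kills order 2)
  C <- matrix(c(0, -0.2, 0.2, 0), 2, 2)
  expect_equal(solenoidal_series(C, 0.01, 2)$value, 0.01 * C, tolerance = 1e-15)
  # antisymmetry of the truncation holds exactly, any C, heterogeneous Gamma
  sys <- canonical_system(seed = 6)
  G <- diag(seq(0.005, 0.03, length.out = 6), 6)
  Q2 <- solenoidal_series(sys$C, G, 2)$value
  expect_equal(Q2, -t(Q2), tolerance = 1e-16)
})

test_that("blanket inverse series matches the scalar closed form", {
  # n_b = 1: exact (Sigma*_bb)^{-1} from the solve, series = sigma^-2 (1 - C_bb)
  p <- partition(1, 1, 0, 1)
  sys <- generate_random_system("unconstrained", p, epsilon = 0.05,
                                sigma = 0.1, seed = 9)
  ser <- blanket_inverse_series(sys$C, 0.1, p, 1)
  expect_equal(ser$value[1, 1], 100 * (1 - sys$C[2, 2]))
  exact <- 1 / stationary_density(sys)$Sigma[2, 2]
  expect_lt(abs(ser$value[1, 1] - exact), 100 * 0.05^2 * 4)
  expect_equal(blanket_inverse_series(matrix(0, 3, 3), 0.1,
                                      partition(1, 1, 0, 1), 1)$value,
               matrix(100, 1, 1))
})

test_that("series truncation errors scale at their design order", {
  # halving epsilon divides the order-k truncation error by ~2^(k+1);
  # per-seed ratios fluctuate with the sign pattern, medians are tight
  seeds <- 1:20
  expected <- c(Sigma = 8, H = 8, Q = 8, SigmaBBinv = 4)
  for (q in names(expected)) {
    r <- vapply(seeds, function(s)
      series_truncation_error("canonical", p2112, 0.1, 0.1, s, q) /
        series_truncation_error("canonical", p2112, 0.05, 0.1, s, q),
      numeric(1))
    expect_gt(median(r), expected[[q]] * 0.7)
    expect_lt(median(r), expected[[q]] * 1.3)
  }
})

test_that("homogeneous noise rescaling scales Sigma and Q linearly", {
  sys <- canonical_system(seed = 12, sigma = 0.1)
  sys4 <- canonical_system(seed = 12, sigma = 0.2)   # Gamma scaled by 4
  d <- stationary_density(sys)
  d4 <- stationary_density(sys4)
  expect_equal(d4$Sigma, 4 * d$Sigma, tolerance = 1e-10)
  expect_equal(d4$Q, 4 * d$Q, tolerance = 1e-10)
  # scale-free audit residuals are unchanged
  expect_equal(markov_blanket_residual(d4$H, p2112)$relative,
               markov_blanket_residual(d$H, p2112)$relative, tolerance = 1e-9)
})
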