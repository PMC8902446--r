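test_that("conditional moments reduce to textbook Gaussian conditioning", {
  # diagonal covariance: independence, zero gains, mode at the set-point
  sys <- make_system(-diag(6), gamma = 0.01, partition = p2112,
                     rho = seq(0.1, 0.6, by = 0.1))
  m <- conditional_moments(stationary_density(sys))
  expect_equal(frob(m$gain_y), 0)
  expect_equal(conditional_mode(m, c(5, -3)), c(0.1, 0.2))
  expect_false(m$used_pseudoinverse)

  # scalar y, scalar blanket, correlation c: gain_y = c
  p <- partition(1, 1, 0, 0)
  c_ <- 0.4
  J <- -solve(matrix(c(1, c_, c_, 1), 2, 2))   # symmetric J with Sigma* = -J^-1 Gamma
  sys2 <- make_system(J, gamma = 1, partition = p)
  m2 <- conditional_moments(stationary_density(sys2))
  expect_equal(m2$gain_y[1, 1], c_, tolerance = 1e-12)
  expect_equal(m2$cond_cov_y[1, 1], 1 - c_^2, tolerance = 1e-12)
})

test_that("conditional gain reproduces the ensemble regression of y on b", {
  sys <- chain_system()
  d <- stationary_density(sys)
  m <- conditional_moments(d)
  Z <- withr::with_seed(77, MASS::mvrnorm(2e4, mu = d$rho, Sigma = d$Sigma))
  fit <- lm(Z[, 1:2] ~ Z[, 3:4])
  expect_lt(max(abs(unname(t(coef(fit)[-1, ])) - m$gain_y)), 0.03)
})

test_that("Schur conditional covariance and precision-block form agree only under a Markov blanket", {
  m_exact <- conditional_moments(stationary_density(decoupled_system()))
  expect_lt(m_exact$schur_precision_gap, 1e-12)
  m_generic <- conditional_moments(stationary_density(canonical_system(seed = 2)))
  expect_gt(m_generic$schur_precision_gap, 0)
})

test_that("sigma map synchronises the conditional modes and inverts on its range", {
  sys <- canonical_system(seed = 11)
  m <- conditional_moments(stationary_density(sys))
  sm <- sigma_map(m)
  si <- sigma_inverse(m)
  for (b in list(c(0.05, -0.03), c(-0.2, 0.02))) {
    expect_equal(predict(sm, conditional_mode(m, b, "x")),
                 conditional_mode(m, b, "y"), tolerance = 1e-12)
  }
  v <- c(0.3, -0.2)
  expect_lt(max(abs(predict(si, predict(sm, v)) - v)), 1e-10)

  # centering: sigma maps rho_x to rho_y
  rho <- seq(-0.3, 0.2, length.out = 6)
  sysr <- make_system(sys$J, rho = rho, gamma = sys$sigma^2, partition = p2112)
  mr <- conditional_moments(stationary_density(sysr))
  expect_equal(predict(sigma_map(mr), mr$rho_x), mr$rho_y, tolerance = 1e-12)

  # rank condition: n_x < n_b leaves the map undefined
  pbad <- partition(2, 1, 2, 1)
  sysb <- generate_random_system("canonical", pbad, epsilon = 0.1, seed = 3)
  mb <- conditional_moments(stationary_density(sysb))
  expect_error(sigma_map(mb), class = "fep_mapping_error")
})

test_that("surprise has the Gaussian closed form", {
  sys <- make_system(-diag(6), gamma = 1, partition = p2112)  # Sigma*_bb = I_2
  d <- stationary_density(sys)
  expect_equal(surprise(c(0, 0), d), log(2 * pi), tolerance = 1e-12)
  # one standard deviation costs exactly 1/2 nat for a scalar blanket
  sys1 <- withr::with_seed(21, make_system(
    -diag(3) + matrix(runif(9, -0.2, 0.2), 3, 3),
    rho = c(0.1, -0.2, 0.3), gamma = 0.01, partition = partition(1, 1, 0, 1)))
  d1 <- stationary_density(sys1)
  sd_b <- sqrt(d1$Sigma[2, 2])
  b0 <- d1$rho[2]
  expect_equal(surprise(b0 + sd_b, d1) - surprise(b0, d1), 0.5,
               tolerance = 1e-12)
  # mean surprise over NESS samples ~ differential entropy of the blanket
  sys2 <- chain_system()
  d2 <- stationary_density(sys2)
  B <- withr::with_seed(5, MASS::mvrnorm(2e4, d2$rho, d2$Sigma))[, 3:4]
  mean_s <- mean(apply(B, 1, surprise, density = d2))
  Sbb <- d2$Sigma[3:4, 3:4]
  entropy <- 0.5 * log(det(2 * pi * exp(1) * Sbb))
  expect_equal(mean_s, entropy, tolerance = 0.02)
})

test_that("free energy bounds surprise, attains it at the conditional, and has exact gradients", {
  sys <- canonical_system(seed = 11)
  d <- stationary_density(sys)
  m <- conditional_moments(d)
  b <- c(0.04, -0.06)
  opt <- free_energy(conditional_mode(m, b), m$cond_cov_y, b, d, moments = m)
  expect_equal(opt$kl, 0)
  expect_equal(opt$free_energy, opt$surprise)
  expect_equal(opt$gradient, c(0, 0))

  for (theta in list(c(0.1, 0), c(-0.3, 0.2))) {
    fe <- free_energy(theta, m$cond_cov_y, b, d, moments = m)
    expect_gt(fe$free_energy, fe$surprise)
    fd <- fd_gradient(function(th)
      free_energy(th, m$cond_cov_y, b, d, moments = m)$free_energy, theta)
    expect_equal(fe$gradient, fd, tolerance = 1e-6)
  }
  # mis-scaled variational covariance also costs free energy
  fe2 <- free_energy(conditional_mode(m, b), 2 * m$cond_cov_y, b, d, moments = m)
  expect_gt(fe2$kl, 0)
  expect_error(free_energy(c(0, 0), -diag(2), b, d, moments = m),
               class = "fep_degenerate_error")
})

test_that("marginal flows vanish at the set-point and average the true drift", {
  sys <- canonical_system(seed = 11)
  d <- stationary_density(sys)
  m <- conditional_moments(d)
  expect_equal(marginal_flow_y(m$rho_b, sys, m), c(0, 0), ignore_attr = TRUE)
  expect_equal(marginal_flow_x(m$rho_b, sys, m), c(0, 0), ignore_attr = TRUE)
  expect_false(attr(marginal_flow_y(m$rho_b, sys, m), "mask_violation"))

  # Monte-Carlo: E[f_y(y, b) | b] over y ~ p(y | b)
  b <- c(0.05, -0.02)
  mu <- conditional_mode(m, b, "y")
  Y <- withr::with_seed(9, MASS::mvrnorm(2e4, mu, m$cond_cov_y))
  p <- p2112
  FY <- sys$J[p$idx$y, p$idx$y] %*% (t(Y) - 0) +
    matrix(sys$J[p$idx$y, p$idx$b] %*% b, 2, nrow(Y))
  expect_equal(rowMeans(FY), as.numeric(marginal_flow_y(b, sys, m)),
               tolerance = 0.01, ignore_attr = TRUE)

  # a coupling C_yx flags the conditional average instead of refusing
  Cv <- sys$C; Cv[1, 5] <- 0.1
  sysv <- make_system(-diag(6) + Cv, gamma = sys$sigma^2, partition = p2112)
  expect_true(attr(marginal_flow_y(b, sysv, conditional_moments(stationary_density(sysv))),
                   "mask_violation"))
})

test_that("the gradient-flow identity is exact under MB + block-diagonal Q and degrades linearly", {
  expect_lt(gradient_flow_identity_residual(decoupled_system()), 1e-8)
  # generic canonical systems violate it at O(epsilon)
  r1 <- vapply(1:10, function(s)
    gradient_flow_identity_residual(canonical_system(seed = s, epsilon = 0.1)),
    numeric(1))
  r2 <- vapply(1:10, function(s)
    gradient_flow_identity_residual(canonical_system(seed = s, epsilon = 0.05)),
    numeric(1))
  expect_true(all(r1 > 0))
  expect_equal(median(r1 / r2), 2, tolerance = 0.35)
})

test_that("phi connects the two conditional average flows but differs from grad sigma", {
  for (s in c(4, 11, 19)) {
    sys <- canonical_system(seed = s)
    m <- conditional_moments(stationary_density(sys))
    phi <- phi_map(sys, m)
    for (b in list(c(0.03, 0.02), c(-0.1, 0.04))) {
      expect_equal(predict(phi, marginal_flow_x(b, sys, m)),
                   as.numeric(marginal_flow_y(b, sys, m)), tolerance = 1e-10)
    }
    expect_gt(flow_map_mismatch(sys, m), 1e-2)
  }
  # rank condition n_x = n_b fails
  pbad <- partition(2, 1, 2, 1)
  sysb <- generate_random_system("canonical", pbad, epsilon = 0.1, seed = 3)
  expect_error(phi_map(sysb, conditional_moments(stationary_density(sysb))),
               class = "fep_mapping_error")
})
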