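# Shared fixtures, built in code.

p2112 <- partition(2, 1, 1, 2)

# The reference weakly-coupled symmetric-chain configuration used for the
# trajectory-divergence studies: n_y = n_x = 2, n_a = n_s = 1, couplings
# +/- 0.1, noise scale 0.1.
chain_system <- function(seed = 42) {
  generate_random_system("symmetric_chain", p2112, epsilon = 0.1,
                         sigma = 0.1, seed = seed)
}

canonical_system <- function(seed = 1, epsilon = 0.1, sigma = 0.1) {
  generate_random_system("canonical", p2112, epsilon = epsilon,
                         sigma = sigma, seed = seed)
}

# A system whose drift decouples all four blocks (couplings only inside y):
# exact Markov blanket and block-diagonal Q by construction.
decoupled_system <- function() {
  J <- -diag(6)
  J[1, 2] <- 0.3
  J[2, 1] <- -0.2
  make_system(J, gamma = 0.01, partition = p2112)
}

# Random stable unconstrained system of dimension n (shifted-diagonal drift
# keeps it Hurwitz), heterogeneous noise optional.
random_stable_system <- function(n, seed, homogeneous = TRUE) {
  withr::with_seed(seed, {
    C <- matrix(runif(n^2, -1, 1), n, n) * 0.4 / sqrt(n)
    gamma <- if (homogeneous) 0.01 else diag(runif(n, 0.005, 0.05), n)
    ny <- max(1, floor(n / 4)); ns <- max(1, floor(n / 4))
    na <- max(1, floor(n / 4)); nx <- n - ny - ns - na
    make_system(-diag(n) + C, gamma = gamma,
                partition = partition(ny, ns, na, nx))
  })
}
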