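# Independent oracles, deliberately written without reusing package internals.

# Brute-force continuous Lyapunov solve of J X + X J' = W by Kronecker
# vectorization: (I (x) J + J (x) I) vec(X) = vec(W).
lyap_kron <- function(J, W) {
  n <- nrow(J)
  K <- diag(n) %x% J + J %x% diag(n)
  matrix(solve(K, as.vector(W)), n, n)
}

# Closed-form deterministic solution of dz/dt = J (z - rho): z(t) via the
# matrix exponential.
expm_solution <- function(J, rho, z0, t) {
  as.numeric(Matrix::expm(J * t) %*% (z0 - rho)) + rho
}

frob <- function(M) sqrt(sum(M^2))

# Central finite differences of a scalar function.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
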