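#' Solve a continuous Lyapunov equation A X + X A' = W
#'
#' Spectral solver: with the eigendecomposition `A = V L V^{-1}` the
#' transformed unknown `Y = V^{-1} X V^{-T}` satisfies
#' `Y_ij = (V^{-1} W V^{-T})_ij / (L_i + L_j)`, so `X = Re(V Y V^T)`.
#' Requires `A` diagonalizable with no eigenvalue pair summing to zero
#' (guaranteed for Hurwitz `A`); a dense Kronecker-vectorization solve of
#' `(I (x) A + A (x) I) vec(X) = vec(W)` is used as fallback when the
#' eigenbasis is numerically ill-conditioned.
#'
#' @param A Square real matrix.
#' @param W Square real matrix (same dimension).
#' @return The solution matrix `X`.
#' @keywords internal
#' @export
solve_lyapunov <- function(A, W) {
  n <- nrow(A)
  ev <- eigen(A)
  V <- ev$vectors
  ok <- tryCatch({
    Vi <- solve(V)
    kappa <- sqrt(sum(Mod(V)^2)) * sqrt(sum(Mod(Vi)^2))
    is.finite(kappa) && kappa < 1e8
  }, error = function(e) FALSE)
  if (ok) {
    M <- Vi %*% W %*% t(Vi)
    denom <- outer(ev$values, ev$values, `+`)
    X <- V %*% (M / denom) %*% t(V)
    return(Re(X))
  }
  # fallback: dense vectorized solve, O(n^6) but exact for any Hurwitz A
  K <- diag(n) %x% A + A %x% diag(n)
  matrix(solve(K, as.vector(W)), n, n)
}

#' Non-equilibrium steady state of a partitioned linear system
#'
#' Solves the continuous Lyapunov equation `J S + S J' + 2 Gamma = 0` for
#' the stationary covariance `S = Sigma*`, forms the precision
#' `H = (Sigma*)^{-1}` (via a Cholesky-based solve, never an explicit
#' inverse of an unsymmetrized matrix), and the solenoidal matrix under the
#' convention `Q = J Sigma* + Gamma`, which is antisymmetric by the
#' Lyapunov identity and reconstructs the drift as `J = (Q - Gamma) H`.
#' The decomposition splits the drift into a dissipative part `-Gamma H`
#' and a circulating part `Q H`; symmetric `J` (detailed balance) gives
#' `Q = 0`.
#'
#' @param system An `fep_system` (Hurwitz drift required).
#' @param q_sign Sign convention for the solenoidal matrix: `"positive"`
#'   (default, `Q = J Sigma* + Gamma`) or `"negative"` for the opposite
#'   global sign.
#' @return Object of class `fep_stationary`: list with `Sigma`, `H`, `Q`,
#'   `rho`, `partition`, and `residuals` — a named list with
#'   `lyapunov` (`||J S + S J' + 2 Gamma||_F`), `antisymmetry`
#'   (`||Q + Q'||_F`) and `reconstruction` (`||(Q - Gamma) H - J||_F`).
#' @examples
#' sys <- make_system(-diag(4), gamma = 0.01, partition = partition(1, 1, 1, 1))
#' ness <- stationary_density(sys)
#' ness$Sigma[1, 1]   # 0.01
#' @export
stationary_density <- function(system, q_sign = c("positive", "negative")) {
  stopifnot(inherits(system, "fep_system"))
  q_sign <- match.arg(q_sign)
  n <- system$partition$n
  Gamma <- gamma_matrix(system)
  Sigma <- solve_lyapunov(system$J, -2 * Gamma)
  Sigma <- (Sigma + t(Sigma)) / 2
  lyap_res <- fnorm(system$J %*% Sigma + Sigma %*% t(system$J) + 2 * Gamma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    abort("stationary covariance is numerically singular (degenerate density); precision unavailable",
          class = "fep_degenerate_error")
  }
  H <- chol2inv(chol(Sigma))
  H <- (H + t(H)) / 2
  Q <- system$J %*% Sigma + Gamma
  if (q_sign == "negative") Q <- -Q
  structure(
    list(Sigma = Sigma, H = H, Q = Q, rho = system$rho,
         partition = system$partition, gamma = system$gamma,
         q_sign = q_sign,
         residuals = list(
           lyapunov = lyap_res,
           antisymmetry = fnorm(Q + t(Q)),
           reconstruction = fnorm((Q * (if (q_sign == "negative") -1 else 1) - Gamma) %*% H - system$J))),
    class = "fep_stationary")
}

#' @export
print.fep_stationary <- function(x, ...) {
  cat(sprintf("<fep_stationary> n = %d\n", nrow(x$Sigma)))
  cat(sprintf("  residuals: lyapunov %.3g, antisymmetry %.3g, reconstruction %.3g\n",
              x$residuals$lyapunov, x$residuals$antisymmetry,
              x$residuals$reconstruction))
  invisible(x)
}

#' Solenoidal matrix of a stationary density
#'
#' Convenience accessor: computes (or re-signs) `Q = J Sigma* + Gamma` from
#' a system and its stationary covariance.
#' @inheritParams stationary_density
#' @param Sigma Stationary covariance; solved from `system` when omitted.
#' @return Antisymmetric matrix `Q`.
#' @export
solve_solenoidal <- function(system, Sigma = NULL,
                             q_sign = c("positive", "negative")) {
  q_sign <- match.arg(q_sign)
  if (is.null(Sigma)) Sigma <- stationary_density(system)$Sigma
  Q <- system$J %*% Sigma + gamma_matrix(system)
  if (q_sign == "negative") -Q else Q
}

new_series <- function(quantity, order, value, epsilon_scale = NA_real_) {
  structure(list(quantity = quantity, order = as.integer(order),
                 value = value, epsilon_scale = epsilon_scale),
            class = "fep_series")
}

#' @export
print.fep_series <- function(x, ...) {
  cat(sprintf("<fep_series> %s, order %d, %d x %d\n", x$quantity, x$order,
              nrow(x$value), ncol(x$value)))
  invisible(x)
}

as_gamma <- function(gamma, n) {
  if (is.matrix(gamma)) {
    stopifnot(all(dim(gamma) == n))
    gamma
  } else if (length(gamma) == 1) diag(as.numeric(gamma), n)
  else diag(as.numeric(gamma), n)
}

#' Weak-coupling power series for the stationary covariance
#'
#' With `J = -I + C` the Lyapunov equation rearranges to the exact fixed
#' point `Sigma = Gamma + (C Sigma + Sigma C')/2`; iterating from `Gamma`
#' and collecting terms by total power of `C` gives the truncation
#' `Sigma_k = sum_{m=0}^{k} T_m` with `T_0 = Gamma` and
#' `T_m = (C T_{m-1} + T_{m-1} C')/2`. The order-2 truncation is
#' `Gamma + (C Gamma + Gamma C')/2 + (C^2 Gamma + 2 C Gamma C' + Gamma C'^2)/4`.
#'
#' @param C Coupling matrix.
#' @param gamma Noise matrix `Gamma` (matrix, diagonal vector, or scalar).
#' @param order Truncation order `k >= 0`.
#' @param epsilon_scale Optional nominal coupling magnitude stored for
#'   error-reporting convenience.
#' @return An `fep_series` with `quantity = "Sigma"`.
#' @export
covariance_series <- function(C, gamma, order, epsilon_scale = NA_real_) {
  stopifnot(order >= 0)
  n <- nrow(C)
  Gamma <- as_gamma(gamma, n)
  term <- Gamma
  total <- Gamma
  for (m in seq_len(order)) {
    term <- (C %*% term + term %*% t(C)) / 2
    total <- total + term
  }
  new_series("Sigma", order, total, epsilon_scale)
}

#' Weak-coupling Neumann series for the stationary precision (Hessian)
#'
#' Homogeneous-noise case `Gamma = sigma^2 I` only. The order-2 truncation is
#' `sigma^{-2} (I - (C + C')/2 + (C'C - C C')/4)`; orders 0 and 1 drop the
#' trailing terms. Heterogeneous `Gamma` is not supported by the printed
#' expansion and raises an error.
#'
#' @param C Coupling matrix.
#' @param sigma Scalar noise scale (`> 0`).
#' @param order Truncation order, `0 <= order <= 2`.
#' @inheritParams covariance_series
#' @return An `fep_series` with `quantity = "H"`.
#' @export
hessian_series <- function(C, sigma, order = 2, epsilon_scale = NA_real_) {
  if (length(sigma) != 1 || sigma <= 0) {
    abort("hessian_series requires homogeneous noise with scalar sigma > 0",
          class = "fep_unsupported_mode_error")
  }
  stopifnot(order >= 0, order <= 2)
  n <- nrow(C)
  H <- diag(n)
  if (order >= 1) H <- H - (C + t(C)) / 2
  if (order >= 2) H <- H + (t(C) %*% C - C %*% t(C)) / 4
  new_series("H", order, H / sigma^2, epsilon_scale)
}

#' Weak-coupling series for the solenoidal matrix
#'
#' `Q = (C Gamma - Gamma C')/2 + (C^2 Gamma - Gamma (C^2)')/4 + O(C^3)`;
#' each truncation is exactly antisymmetric.
#'
#' @inheritParams covariance_series
#' @param order Truncation order, `0 <= order <= 2` (two printed orders).
#' @return An `fep_series` with `quantity = "Q"`.
#' @export
solenoidal_series <- function(C, gamma, order = 2, epsilon_scale = NA_real_) {
  stopifnot(order >= 0, order <= 2)
  n <- nrow(C)
  Gamma <- as_gamma(gamma, n)
  Q <- matrix(0, n, n)
  if (order >= 1) Q <- Q + (C %*% Gamma - Gamma %*% t(C)) / 2
  if (order >= 2) {
    C2 <- C %*% C
    Q <- Q + (C2 %*% Gamma - Gamma %*% t(C2)) / 4
  }
  new_series("Q", order, Q, epsilon_scale)
}

#' Weak-coupling series for the inverse blanket covariance
#'
#' Neumann expansion of `(Sigma*_bb)^{-1}` under homogeneous noise: the
#' order-1 truncation is `sigma^{-2} (I - (C_bb + C_bb')/2)` restricted to
#' the blanket indices `b = (s, a)`.
#'
#' @inheritParams hessian_series
#' @param partition A [partition()] locating the blanket block.
#' @param order Truncation order, `0` or `1`.
#' @return An `fep_series` with `quantity = "SigmaBBinv"` of blanket
#'   dimension.
#' @export
blanket_inverse_series <- function(C, sigma, partition, order = 1,
                                   epsilon_scale = NA_real_) {
  if (length(sigma) != 1 || sigma <= 0) {
    abort("blanket_inverse_series requires homogeneous noise with scalar sigma > 0",
          class = "fep_unsupported_mode_error")
  }
  stopifnot(order >= 0, order <= 1)
  p <- as_partition(partition)
  if (p$n_b < 1) abort("empty blanket", class = "fep_dimension_error")
  Cbb <- blk(C, p, "b", "b")
  V <- diag(p$n_b)
  if (order >= 1) V <- V - (Cbb + t(Cbb)) / 2
  new_series("SigmaBBinv", order, V / sigma^2, epsilon_scale)
}
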