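#' Conditional Gaussian moments given the blanket
#'
#' For a stationary Gaussian density `N(rho, Sigma*)` the conditional mode
#' (equal to the conditional mean) of the external and internal blocks
#' given a blanket state `b = (s, a)` is linear:
#' `m_y(b) = rho_y + G_y (b - rho_b)` with gain
#' `G_y = Sigma*_yb (Sigma*_bb)^-` (Moore–Penrose pseudoinverse when the
#' blanket covariance is singular, flagged), and likewise for `x`.
#' The conditional covariance of `y` uses the Schur complement
#' `Sigma_y|b = Sigma_yy - Sigma_yb (Sigma_bb)^- Sigma_by`, which is
#' correct with or without a Markov blanket; the precision-block form
#' `(H_yy)^{-1}` agrees only when `H_yx = 0`, so both are recorded along
#' with their gap as an additional blanket diagnostic.
#'
#' @param density An [stationary_density()] object.
#' @param partition A [partition()]; defaults to the density's.
#' @return Object of class `fep_cond_moments`: gains `gain_y`, `gain_x`,
#'   centers `rho_y`, `rho_x`, `rho_b`, conditional covariances
#'   `cond_cov_y`, `cond_cov_x`, the precision-block alternative
#'   `cond_cov_y_precision` and `schur_precision_gap`, the blanket blocks
#'   `Sigma_bb`, `Sigma_yb`, `Sigma_xb`, and `used_pseudoinverse`.
#' @export
conditional_moments <- function(density, partition = density$partition) {
  stopifnot(inherits(density, "fep_stationary"))
  p <- as_partition(partition)
  S <- density$Sigma
  Sbb <- blk(S, p, "b", "b")
  Syb <- blk(S, p, "y", "b")
  Sxb <- blk(S, p, "x", "b")
  used_pinv <- FALSE
  Sbb_inv <- tryCatch({
    if (rcond(Sbb) < 1e-12) stop("ill-conditioned")
    chol2inv(chol((Sbb + t(Sbb)) / 2))
  }, error = function(e) {
    used_pinv <<- TRUE
    MASS::ginv(Sbb)
  })
  gain_y <- Syb %*% Sbb_inv
  gain_x <- Sxb %*% Sbb_inv
  cond_cov_y <- blk(S, p, "y", "y") - gain_y %*% t(Syb)
  cond_cov_y <- (cond_cov_y + t(cond_cov_y)) / 2
  cond_cov_x <- blk(S, p, "x", "x") - gain_x %*% t(Sxb)
  cond_cov_x <- (cond_cov_x + t(cond_cov_x)) / 2
  Hyy <- blk(density$H, p, "y", "y")
  cond_cov_y_precision <- tryCatch(solve(Hyy), error = function(e) NULL)
  gap <- if (is.null(cond_cov_y_precision)) NA_real_ else
    fnorm(cond_cov_y - cond_cov_y_precision)
  structure(
    list(gain_y = gain_y, gain_x = gain_x,
         rho_y = density$rho[p$idx$y], rho_x = density$rho[p$idx$x],
         rho_b = density$rho[p$idx$b],
         cond_cov_y = cond_cov_y, cond_cov_x = cond_cov_x,
         cond_cov_y_precision = cond_cov_y_precision,
         schur_precision_gap = gap,
         Sigma_bb = Sbb, Sigma_yb = Syb, Sigma_xb = Sxb,
         partition = p, used_pseudoinverse = used_pinv),
    class = "fep_cond_moments")
}

#' @export
print.fep_cond_moments <- function(x, ...) {
  cat(sprintf("<fep_cond_moments> blanket dim %d -> y: %d, x: %d%s\n",
              x$partition$n_b, x$partition$n_y, x$partition$n_x,
              if (x$used_pseudoinverse) " (pseudoinverse)" else ""))
  invisible(x)
}

#' Conditional mode of the external or internal block
#'
#' @param moments A [conditional_moments()] object.
#' @param b Blanket state vector, or a matrix with one blanket state per
#'   column.
#' @param which `"y"` (external, default) or `"x"` (internal).
#' @return Mode vector, or a matrix of modes (one column per input column).
#' @export
conditional_mode <- function(moments, b, which = c("y", "x")) {
  which <- match.arg(which)
  gain <- if (which == "y") moments$gain_y else moments$gain_x
  center <- if (which == "y") moments$rho_y else moments$rho_x
  if (is.matrix(b)) center + gain %*% (b - moments$rho_b)
  else as.numeric(center + gain %*% (b - moments$rho_b))
}

new_linear_map <- function(A, from_center, to_center, from, to) {
  structure(list(A = A, from_center = from_center, to_center = to_center,
                 from = from, to = to),
            class = "fep_linear_map")
}

#' @export
print.fep_linear_map <- function(x, ...) {
  cat(sprintf("<fep_linear_map> %s -> %s (%d x %d)\n", x$from, x$to,
              nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' @export
predict.fep_linear_map <- function(object, newdata, ...) {
  if (is.matrix(newdata)) object$to_center + object$A %*% (newdata - object$from_center)
  else as.numeric(object$to_center + object$A %*% (newdata - object$from_center))
}

require_square_block <- function(M, name, rank_msg) {
  if (nrow(M) != ncol(M) || rcond(M) < 1e-12) {
    abort(sprintf("mapping undefined: %s must be square and nonsingular (%s)",
                  name, rank_msg),
          class = "fep_mapping_error")
  }
}

#' Synchronisation map between most likely internal and external states
#'
#' The map `sigma` with `m_y(b) = sigma(m_x(b))` exists when `Sigma*_xb`
#' and `Sigma*_bb` are nonsingular; its gradient is the constant matrix
#' `grad sigma = Sigma*_yb (Sigma*_xb)^{-1}`. The inverse map additionally
#' needs `Sigma*_yb` nonsingular. Only the square-block case
#' (`n_x = n_b`, resp. `n_y = n_b`) is supported; other shapes raise a
#' mapping-undefined error naming the violated rank condition.
#'
#' @param moments A [conditional_moments()] object.
#' @return An `fep_linear_map`; apply it with [predict()].
#' @export
sigma_map <- function(moments) {
  require_square_block(moments$Sigma_xb, "Sigma*_xb", "requires n_x = n_b")
  new_linear_map(moments$Sigma_yb %*% solve(moments$Sigma_xb),
                 moments$rho_x, moments$rho_y, "m_x", "m_y")
}

#' @rdname sigma_map
#' @export
sigma_inverse <- function(moments) {
  require_square_block(moments$Sigma_yb, "Sigma*_yb", "requires n_y = n_b")
  new_linear_map(moments$Sigma_xb %*% solve(moments$Sigma_yb),
                 moments$rho_y, moments$rho_x, "m_y", "m_x")
}

#' Surprise of a blanket state
#'
#' Negative log stationary probability of the blanket block,
#' `-log N(b; rho_b, Sigma*_bb)`, in nats.
#'
#' @param b Blanket state vector.
#' @param density An [stationary_density()] object.
#' @param partition A [partition()]; defaults to the density's.
#' @return Scalar surprise.
#' @export
surprise <- function(b, density, partition = density$partition) {
  p <- as_partition(partition)
  Sbb <- blk(density$Sigma, p, "b", "b")
  R <- tryCatch(chol((Sbb + t(Sbb)) / 2), error = function(e)
    abort("blanket covariance is not positive definite",
          class = "fep_degenerate_error"))
  d <- b - density$rho[p$idx$b]
  z <- backsolve(R, d, transpose = TRUE)
  0.5 * sum(z^2) + sum(log(diag(R))) + 0.5 * length(d) * log(2 * pi)
}

#' Variational free energy of a Gaussian model of the environment
#'
#' For the variational family `q(y | theta) = N(theta, Sigma_theta)` the
#' free energy is the surprise of the blanket state plus the KL divergence
#' from `q` to the true conditional `p(y | b) = N(m_y(b), Sigma_y|b)`:
#' `F(theta, b) = -log p(b) + KL(q || p(y|b)) >= -log p(b)`, with equality
#' iff `q` equals the conditional. Because the stationary density is
#' Gaussian, the quadratic (Laplace) form of the surprise is exact here,
#' and the gradient has the closed form
#' `grad_theta F = (Sigma_y|b)^{-1} (theta - m_y(b))`.
#'
#' @param theta Mean of the variational density (length `n_y`).
#' @param Sigma_theta Covariance of the variational density (positive
#'   definite `n_y x n_y`).
#' @param b Blanket state.
#' @param density An [stationary_density()] object.
#' @param partition A [partition()]; defaults to the density's.
#' @param moments Optional precomputed [conditional_moments()].
#' @return Object of class `fep_free_energy`: list with `surprise`, `kl`,
#'   `free_energy` and `gradient`.
#' @examples
#' sys <- generate_random_system("canonical", partition(2, 1, 1, 2), seed = 3)
#' d <- stationary_density(sys)
#' m <- conditional_moments(d)
#' b <- c(0.05, -0.02)
#' fe <- free_energy(conditional_mode(m, b), m$cond_cov_y, b, d)
#' fe$kl    # 0: the bound is attained at the true conditional
#' @export
free_energy <- function(theta, Sigma_theta, b, density,
                        partition = density$partition, moments = NULL) {
  p <- as_partition(partition)
  if (is.null(moments)) moments <- conditional_moments(density, p)
  theta <- as.numeric(theta)
  stopifnot(length(theta) == p$n_y)
  Rq <- tryCatch(chol((Sigma_theta + t(Sigma_theta)) / 2), error = function(e)
    abort("Sigma_theta must be positive definite", class = "fep_degenerate_error"))
  P <- moments$cond_cov_y
  Rp <- chol(P)
  m <- conditional_mode(moments, b, "y")
  d <- theta - m
  Pinv_d <- backsolve(Rp, backsolve(Rp, d, transpose = TRUE))
  # trace(P^-1 Sq): solve column-wise through the Cholesky factor of P
  Pinv_Sq <- backsolve(Rp, backsolve(Rp, (Sigma_theta + t(Sigma_theta)) / 2,
                                     transpose = TRUE))
  kl <- 0.5 * (sum(diag(Pinv_Sq)) + sum(d * Pinv_d) - p$n_y) +
    sum(log(diag(Rp))) - sum(log(diag(Rq)))
  kl <- max(kl, 0)   # clip the tiny negative round-off at the optimum
  s <- surprise(b, density, p)
  structure(
    list(surprise = s, kl = kl, free_energy = s + kl, gradient = Pinv_d,
         theta = theta, b = b),
    class = "fep_free_energy")
}

#' @export
print.fep_free_energy <- function(x, ...) {
  cat(sprintf("<fep_free_energy> F = %.6g = surprise %.6g + KL %.6g\n",
              x$free_energy, x$surprise, x$kl))
  invisible(x)
}

#' Conditional average (marginal) flows of the external and internal blocks
#'
#' The expected drift of `y` over the conditional density `p(y | b)`:
#' `<f_y>_b = J_yy (m_y(b) - rho_y) + J_yb (b - rho_b)`, exact under the
#' canonical mask (where `f_y` does not read `x`). If the mask is violated
#' the additional term `J_yx (m_x(b) - rho_x)` is included and the result
#' carries attribute `mask_violation = TRUE` rather than being refused.
#'
#' @param b Blanket state.
#' @param system The `fep_system`.
#' @param moments A [conditional_moments()] object.
#' @return Flow vector (length `n_y` resp. `n_x`).
#' @export
marginal_flow_y <- function(b, system, moments) {
  p <- system$partition
  J <- system$J
  out <- blk(J, p, "y", "y") %*% (conditional_mode(moments, b, "y") - moments$rho_y) +
    blk(J, p, "y", "b") %*% (b - moments$rho_b)
  violated <- fnorm(blk(system$C, p, "y", "x")) > 0
  if (violated) {
    out <- out + blk(J, p, "y", "x") %*%
      (conditional_mode(moments, b, "x") - moments$rho_x)
  }
  structure(as.numeric(out), mask_violation = violated)
}

#' @rdname marginal_flow_y
#' @export
marginal_flow_x <- function(b, system, moments) {
  p <- system$partition
  J <- system$J
  out <- blk(J, p, "x", "x") %*% (conditional_mode(moments, b, "x") - moments$rho_x) +
    blk(J, p, "x", "b") %*% (b - moments$rho_b)
  violated <- fnorm(blk(system$C, p, "x", "y")) > 0
  if (violated) {
    out <- out + blk(J, p, "x", "y") %*%
      (conditional_mode(moments, b, "y") - moments$rho_y)
  }
  structure(as.numeric(out), mask_violation = violated)
}

# Deterministic quasi-random points: Halton sequence (radical inverse).
halton_matrix <- function(n_points, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  stopifnot(dim <= length(primes))
  radical_inverse <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  sapply(seq_len(dim), function(d)
    vapply(seq_len(n_points), radical_inverse, numeric(1), base = primes[d]))
}

#' Residual of the gradient-flow identity
#'
#' In the regime where the Markov blanket is exact (`H_yx = 0`) and the
#' solenoidal off-blocks `Q_yb`, `Q_yx` vanish, the conditional-average
#' flow of the external block equals a preconditioned free-energy gradient:
#' `<f_y>(theta, b) = (Q_yy - Gamma_yy) (Sigma_y|b)^{-1} (theta - m_y(b))`,
#' because then `J_yy = (Q_yy - Gamma_yy) H_yy`, `J_yb = (Q_yy - Gamma_yy)
#' H_yb` and `(Sigma_y|b)^{-1} = H_yy`. This function probes the identity
#' at deterministic quasi-random `(theta, b)` pairs within ±3 conditional
#' standard deviations and returns the largest relative discrepancy — zero
#' (to solver precision) in the identity regime, growing continuously with
#' the blanket and solenoidal residuals outside it.
#'
#' @param system An `fep_system`.
#' @param density Optional precomputed [stationary_density()].
#' @param n_probe Number of probe points.
#' @return Scalar relative residual.
#' @export
gradient_flow_identity_residual <- function(system, density = NULL, n_probe = 16) {
  if (is.null(density)) density <- stationary_density(system)
  p <- system$partition
  moments <- conditional_moments(density, p)
  Gamma <- gamma_matrix(system)
  rate <- blk(density$Q, p, "y", "y") - blk(Gamma, p, "y", "y")
  P <- moments$cond_cov_y
  sd_b <- sqrt(diag(moments$Sigma_bb))
  sd_y <- sqrt(diag(P))
  U <- halton_matrix(n_probe, p$n_y + p$n_b)
  worst <- 0; scale <- 0
  for (i in seq_len(n_probe)) {
    u <- U[i, ]
    b <- moments$rho_b + 3 * sd_b * (2 * u[seq_len(p$n_b)] - 1)
    m <- conditional_mode(moments, b, "y")
    theta <- m + 3 * sd_y * (2 * u[p$n_b + seq_len(p$n_y)] - 1)
    lhs <- blk(system$J, p, "y", "y") %*% (theta - moments$rho_y) +
      blk(system$J, p, "y", "b") %*% (b - moments$rho_b) +
      blk(system$J, p, "y", "x") %*% (conditional_mode(moments, b, "x") - moments$rho_x)
    rhs <- rate %*% solve(P, theta - m)
    worst <- max(worst, sqrt(sum((lhs - rhs)^2)))
    scale <- max(scale, sqrt(sum(lhs^2)), sqrt(sum(rhs^2)))
  }
  worst / max(scale, .Machine$double.xmin)
}

#' Map between conditional average flows, and its mismatch with grad sigma
#'
#' Both conditional-average flows are linear images of the centered blanket
#' state: `<f_y>_b = (J_yy G_y + J_yb)(b - rho_b)` and
#' `<f_x>_b = (J_xx G_x + J_xb)(b - rho_b)` with gains
#' `G_i = Sigma*_ib (Sigma*_bb)^{-1}`. The connecting map is therefore
#' `phi = (J_yy G_y + J_yb)(J_xx G_x + J_xb)^{-1}`, defined in the
#' square-block case `n_y = n_x = n_b`. Generically `phi` differs from the
#' synchronisation-map gradient `grad sigma = Sigma*_yb (Sigma*_xb)^{-1}`;
#' [flow_map_mismatch()] returns `||phi - grad sigma|| / ||grad sigma||`.
#'
#' @param system An `fep_system`.
#' @param moments A [conditional_moments()] object.
#' @return `phi_map()`: an `fep_linear_map` acting on centered internal
#'   flows; `flow_map_mismatch()`: scalar relative mismatch.
#' @export
phi_map <- function(system, moments) {
  p <- system$partition
  if (p$n_y != p$n_b || p$n_x != p$n_b) {
    abort("mapping undefined: phi requires square blocks (n_y = n_x = n_b)",
          class = "fep_mapping_error")
  }
  require_square_block(moments$Sigma_bb, "Sigma*_bb", "requires nonsingular blanket covariance")
  require_square_block(moments$Sigma_xb, "Sigma*_xb", "requires n_x = n_b")
  require_square_block(moments$Sigma_yb, "Sigma*_yb", "requires n_y = n_b")
  Ay <- blk(system$J, p, "y", "y") %*% moments$gain_y + blk(system$J, p, "y", "b")
  Ax <- blk(system$J, p, "x", "x") %*% moments$gain_x + blk(system$J, p, "x", "b")
  if (rcond(Ax) < 1e-12) {
    abort("mapping undefined: internal flow coefficient J_xx G_x + J_xb is singular",
          class = "fep_mapping_error")
  }
  new_linear_map(Ay %*% solve(Ax), rep(0, p$n_x), rep(0, p$n_y),
                 "<f_x>_b", "<f_y>_b")
}

#' @rdname phi_map
#' @export
flow_map_mismatch <- function(system, moments) {
  phi <- phi_map(system, moments)$A
  grad_sigma <- sigma_map(moments)$A
  fnorm(phi - grad_sigma) / fnorm(grad_sigma)
}
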