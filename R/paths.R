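state_names <- function(p) {
  unlist(lapply(BLOCKS, function(bl) {
    k <- p[[paste0("n_", bl)]]
    if (k == 0) character(0) else paste0(bl, seq_len(k))
  }))
}

#' Simulate a trajectory of a partitioned linear Langevin system
#'
#' Euler–Maruyama discretization of `dz/dt = J (z - rho) + omega_t`:
#' `z_{t+dt} = z_t + dt J (z_t - rho) + sqrt(2 dt) Gamma^{1/2} xi_t` with
#' standard normal `xi_t`, so the driving noise has per-step covariance
#' `2 Gamma dt`. With zero noise and `z_0 = rho` the path is constantly
#' `rho`; with zero noise and any start it follows the matrix-exponential
#' solution up to `O(dt)`.
#'
#' @param system An `fep_system`.
#' @param z0 Initial state; defaults to `rho`.
#' @param dt Time step (`dt * max |eigenvalue of J| < 0.1` recommended; a
#'   warning and an `unstable_step` attribute flag larger steps).
#' @param t_end Final time; the grid is `0, dt, ..., t_end`.
#' @param seed Integer seed; fully determines the path.
#' @return A tibble of class `fep_trajectory` with column `t` and one
#'   column per state, named by block (`y1, ..., s1, ..., a1, ..., x1, ...`),
#'   with attributes `system`, `dt`, `seed`, `scheme` and `unstable_step`.
#' @export
simulate_system <- function(system, z0 = NULL, dt = 1e-2, t_end = 100,
                            seed = NULL) {
  p <- system$partition
  if (dt <= 0) abort("dt must be positive", class = "fep_dimension_error")
  if (is.null(z0)) z0 <- system$rho
  stopifnot(length(z0) == p$n)
  lam <- max(abs(eigen(system$J, only.values = TRUE)$values))
  unstable <- dt * lam >= 0.1
  if (unstable) {
    warn(sprintf("dt * max|eig(J)| = %.3g >= 0.1; step may be inaccurate", dt * lam))
  }
  n_steps <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  sqrt_noise <- sqrt(2 * dt * system$gamma)
  run <- function() {
    Z <- matrix(0, n_steps + 1, p$n)
    z <- as.numeric(z0)
    Z[1, ] <- z
    for (k in seq_len(n_steps)) {
      z <- z + dt * as.numeric(system$J %*% (z - system$rho)) +
        sqrt_noise * rnorm(p$n)
      Z[k + 1, ] <- z
    }
    Z
  }
  Z <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  colnames(Z) <- state_names(p)
  out <- dplyr::bind_cols(tibble(t = times), as_tibble(Z))
  class(out) <- c("fep_trajectory", class(out))
  attr(out, "system") <- system
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  attr(out, "scheme") <- "euler_maruyama"
  attr(out, "unstable_step") <- unstable
  out
}

#' Simulate an ensemble and return the final states
#'
#' Vectorized Euler–Maruyama over many members at once (all members share
#' the step loop); used for checking the stationary moments of the
#' integrator against the Lyapunov solution.
#'
#' @inheritParams simulate_system
#' @param members Number of ensemble members.
#' @return `members x n` matrix of states at `t_end`.
#' @export
simulate_ensemble_states <- function(system, members, dt = 1e-2, t_end = 30,
                                     z0 = NULL, seed = NULL) {
  p <- system$partition
  if (is.null(z0)) z0 <- system$rho
  n_steps <- ceiling(t_end / dt)
  sqrt_noise <- sqrt(2 * dt * system$gamma)
  run <- function() {
    Z <- matrix(z0, p$n, members)
    for (k in seq_len(n_steps)) {
      Z <- Z + dt * (system$J %*% (Z - system$rho)) +
        sqrt_noise * matrix(rnorm(p$n * members), p$n, members)
    }
    t(Z)
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

traj_states <- function(trajectory) {
  as.matrix(trajectory[, setdiff(names(trajectory), "t"), drop = FALSE])
}

traj_blanket <- function(trajectory, p) {
  traj_states(trajectory)[, p$idx$b, drop = FALSE]
}

#' True conditional-mode path along a trajectory
#'
#' Applies the fixed linear conditioning map pointwise:
#' `m_y(b_t) = rho_y + G_y (b_t - rho_b)` for the realized blanket path, so
#' increments satisfy `m_y(b_{t+dt}) - m_y(b_t) = G_y (b_{t+dt} - b_t)`
#' exactly. This path is stationary whenever the trajectory is.
#'
#' @param trajectory A [simulate_system()] tibble.
#' @param moments A [conditional_moments()] object.
#' @return Tibble `(t, my1, ..., my<n_y>)`.
#' @export
true_mode_path <- function(trajectory, moments) {
  p <- moments$partition
  B <- traj_blanket(trajectory, p)
  M <- t(moments$rho_y + moments$gain_y %*% (t(B) - moments$rho_b))
  colnames(M) <- paste0("my", seq_len(p$n_y))
  dplyr::bind_cols(tibble(t = trajectory$t), as_tibble(M))
}

#' Marginal-flow surrogate path
#'
#' Integrates (Euler, on the trajectory's own grid) the surrogate dynamics
#' prescribed by reading the conditional average flow as an actual velocity:
#' `d m~_y / dt = (J_yy G_y + J_yb)(b_t - rho_b)` driven by the realized
#' blanket path. Unlike the true conditional-mode path this accumulates an
#' integral of a stationary process, so its ensemble variance grows
#' diffusively instead of plateauing — the central divergence this package
#' quantifies.
#'
#' @inheritParams true_mode_path
#' @param system The `fep_system` that produced the trajectory.
#' @param m0 Initial value; defaults to `m_y(b_0)` (shared with the true
#'   path).
#' @return Tibble `(t, mt1, ..., mt<n_y>)`.
#' @export
marginal_flow_path <- function(trajectory, system, moments, m0 = NULL) {
  p <- system$partition
  dt <- attr(trajectory, "dt") %||% diff(trajectory$t[1:2])
  B <- traj_blanket(trajectory, p)
  A <- blk(system$J, p, "y", "y") %*% moments$gain_y + blk(system$J, p, "y", "b")
  if (is.null(m0)) m0 <- conditional_mode(moments, B[1, ], "y")
  drive <- t(A %*% (t(B) - moments$rho_b))        # one row per time point
  n_t <- nrow(B)
  M <- matrix(0, n_t, p$n_y)
  M[1, ] <- m0
  if (n_t > 1) {
    increments <- drive[-n_t, , drop = FALSE] * dt
    M[-1, ] <- matrix(m0, n_t - 1, p$n_y, byrow = TRUE) +
      apply(increments, 2, cumsum)
  }
  colnames(M) <- paste0("mt", seq_len(p$n_y))
  dplyr::bind_cols(tibble(t = trajectory$t), as_tibble(M))
}

path_values <- function(path) as.matrix(path[, setdiff(names(path), "t"), drop = FALSE])

#' Compare the true conditional-mode path with its marginal-flow surrogate
#'
#' Computes the root-mean-square gap and per-coordinate correlation between
#' the two paths. With an ensemble (the same comparison replicated over
#' noise seeds) it additionally summarises the diffusive growth of the
#' surrogate: the across-member variance of `m~_y(t)` (summed over
#' coordinates), its least-squares growth slope over the second half of the
#' run, the ratio `Var(T) / Var(T/4)` (approximately 4 for diffusive
#' growth), and the plateau `var_bound_true = max_t Var[m_y(b_t)]`.
#'
#' @param m_y_path Tibble from [true_mode_path()].
#' @param m_tilde_path Tibble from [marginal_flow_path()] on the same grid.
#' @param ensemble Optional list of `list(m_y = , m_tilde = )` path pairs
#'   from independent seeds (may include the first pair).
#' @return Object of class `fep_path_comparison` with fields `rmse`, `corr`
#'   (per coordinate), and when an ensemble is given `var_growth_slope`,
#'   `var_ratio`, `var_bound_true`, `median_abs_corr` and the ensemble
#'   variance table `variance` (`t`, `var_m_tilde`, `var_m_y`).
#' @export
compare_paths <- function(m_y_path, m_tilde_path, ensemble = NULL) {
  if (nrow(m_y_path) != nrow(m_tilde_path)) {
    abort("paths must share the same time grid", class = "fep_dimension_error")
  }
  MY <- path_values(m_y_path)
  MT <- path_values(m_tilde_path)
  gap <- MY - MT
  corr <- vapply(seq_len(ncol(MY)), function(j) {
    if (sd(MY[, j]) == 0 || sd(MT[, j]) == 0) 1 else cor(MY[, j], MT[, j])
  }, numeric(1))
  out <- list(rmse = sqrt(mean(gap^2)), corr = corr,
              times = m_y_path$t, n_members = 1L)
  if (!is.null(ensemble)) {
    arr_y <- lapply(ensemble, function(e) path_values(e$m_y))
    arr_t <- lapply(ensemble, function(e) path_values(e$m_tilde))
    n_t <- nrow(arr_y[[1]])
    var_at <- function(mats, k) {
      X <- do.call(rbind, lapply(mats, function(m) m[k, , drop = FALSE]))
      sum(apply(X, 2, var))
    }
    var_m_y <- vapply(seq_len(n_t), function(k) var_at(arr_y, k), numeric(1))
    var_m_tilde <- vapply(seq_len(n_t), function(k) var_at(arr_t, k), numeric(1))
    times <- m_y_path$t
    half <- times >= times[n_t] / 2
    fit <- lm(v ~ t, data = data.frame(t = times[half], v = var_m_tilde[half]))
    kq <- which.min(abs(times - times[n_t] / 4))
    member_corr <- vapply(seq_along(ensemble), function(i) {
      my <- arr_y[[i]]; mt <- arr_t[[i]]
      median(vapply(seq_len(ncol(my)), function(j)
        abs(cor(my[, j], mt[, j])), numeric(1)))
    }, numeric(1))
    out$variance <- tibble(t = times, var_m_tilde = var_m_tilde, var_m_y = var_m_y)
    out$var_growth_slope <- coef(fit)[[2]]
    out$var_ratio <- var_m_tilde[n_t] / var_m_tilde[kq]
    out$var_bound_true <- max(var_m_y)
    out$median_abs_corr <- median(member_corr)
    out$n_members <- length(ensemble)
  }
  structure(out, class = "fep_path_comparison")
}

#' @export
print.fep_path_comparison <- function(x, ...) {
  cat(sprintf("<fep_path_comparison> rmse %.4g, corr [%s], %d member(s)\n",
              x$rmse, paste(sprintf("%.2f", x$corr), collapse = ", "),
              x$n_members))
  if (!is.null(x$var_growth_slope)) {
    cat(sprintf("  surrogate Var growth slope %.3g, Var(T)/Var(T/4) = %.2f, true plateau %.3g\n",
                x$var_growth_slope, x$var_ratio, x$var_bound_true))
  }
  invisible(x)
}

#' @describeIn compare_paths One-row tibble of the comparison metrics.
#' @param x An `fep_path_comparison`.
#' @param ... Unused.
#' @export
glance.fep_path_comparison <- function(x, ...) {
  tibble(rmse = x$rmse, median_abs_corr_first = median(abs(x$corr)),
         n_members = x$n_members,
         var_growth_slope = x$var_growth_slope %||% NA_real_,
         var_ratio = x$var_ratio %||% NA_real_,
         var_bound_true = x$var_bound_true %||% NA_real_,
         median_abs_corr = x$median_abs_corr %||% NA_real_)
}

#' Ensemble divergence between mode path and marginal-flow surrogate
#'
#' Replicates a system's trajectory over independent seeds, builds the two
#' derived paths for every member, and returns their [compare_paths()]
#' summary (first member as the reference pair, all members as ensemble).
#'
#' @param system An `fep_system`.
#' @param members Number of independent trajectories.
#' @param dt,t_end Integration grid.
#' @param seed Base seed; member `i` uses `seed + i - 1`.
#' @param z0 Shared initial state (defaults to `rho`).
#' @return An `fep_path_comparison` with ensemble fields.
#' @export
flow_divergence_ensemble <- function(system, members = 32, dt = 1e-2,
                                     t_end = 100, seed = 1, z0 = NULL) {
  moments <- conditional_moments(stationary_density(system))
  pairs <- lapply(seq_len(members), function(i) {
    traj <- simulate_system(system, z0 = z0, dt = dt, t_end = t_end,
                            seed = seed + i - 1)
    list(m_y = true_mode_path(traj, moments),
         m_tilde = marginal_flow_path(traj, system, moments))
  })
  compare_paths(pairs[[1]]$m_y, pairs[[1]]$m_tilde, ensemble = pairs)
}

#' First-order coefficient matrices of the two path derivatives
#'
#' To first order in the couplings (homogeneous noise, canonical mask) the
#' true conditional-mode derivative is driven by
#' `A_true = -(C_yb + C_by')/2` applied to `(b_t - rho_b - omega_b)`,
#' whereas the marginal-flow surrogate is driven by
#' `A_tilde = -(-C_yb + C_by')/2` — the sign of the `C_yb` term flips, and
#' the noise term is dropped. The exact counterparts (any coupling
#' strength) are `A_true_exact = G_y (J_by G_y + J_bb + J_bx G_x)` and
#' `A_tilde_exact = J_yy G_y + J_yb`; both differ from the first-order
#' matrices by `O(epsilon^2)`. When all between-block couplings touching
#' the blanket are symmetric (`C_yb = C_by'`), `A_tilde = 0` while
#' `A_true = -C_yb` stays non-zero.
#'
#' @param system An `fep_system` with homogeneous noise and the canonical
#'   mask (possibly with further zeros).
#' @return Named list of matrices `A_true`, `A_tilde`, `A_true_exact`,
#'   `A_tilde_exact`.
#' @export
first_order_flow_matrices <- function(system) {
  p <- system$partition
  require_canonical_mask(system$C, p)
  if (is.na(system$sigma)) {
    abort("first-order flow matrices assume homogeneous noise",
          class = "fep_unsupported_mode_error")
  }
  Cyb <- blk(system$C, p, "y", "b")
  Cby <- blk(system$C, p, "b", "y")
  moments <- conditional_moments(stationary_density(system))
  A_true_exact <- moments$gain_y %*%
    (blk(system$J, p, "b", "y") %*% moments$gain_y +
       blk(system$J, p, "b", "b") +
       blk(system$J, p, "b", "x") %*% moments$gain_x)
  A_tilde_exact <- blk(system$J, p, "y", "y") %*% moments$gain_y +
    blk(system$J, p, "y", "b")
  list(A_true = -(Cyb + t(Cby)) / 2,
       A_tilde = -(-Cyb + t(Cby)) / 2,
       A_true_exact = A_true_exact,
       A_tilde_exact = A_tilde_exact)
}

#' Bivariate spiral-flow demonstration
#'
#' A two-variable system with states `(y, b)` and drift
#' `J = [[-1, c], [-c, -1]]`: a globally attracting spiral around the
#' origin (eigenvalues `-1 ± ci`) whose circulation is pure solenoidal
#' flow, `Q = sigma^2 c [[0, 1], [-1, 0]]`. Because the stationary
#' covariance is `sigma^2 I`, the conditional mode of `y` given `b` is 0
#' and the conditional average flow of `y` reduces to `c b`: read as a
#' velocity for `y` it points away from the conditional mode whenever
#' `c b` and the current deviation agree in sign — suggesting monotone
#' growth of `m_y^2` — while every true trajectory decays to the origin in
#' expectation. The returned fields make that sign mismatch explicit.
#'
#' @param c_strength Rotation strength `c != 0`.
#' @param sigma Noise scale.
#' @param grid Grid of values for each axis; defaults to 21 points spanning
#'   ±3 standard deviations.
#' @return List with `flow_field` (tibble `y, b, dy, db, radial` — the true
#'   flow and its radial component), `conditional_flow` (tibble
#'   `b, flow_y`), the solenoidal matrix `Q`, the drift `J`, its
#'   eigenvalues, and the system.
#' @export
bivariate_demo <- function(c_strength = 0.5, sigma = 0.1, grid = NULL) {
  if (c_strength == 0) warn("c_strength = 0 gives an equilibrium system (Q = 0)")
  if (is.null(grid)) grid <- seq(-3 * sigma, 3 * sigma, length.out = 21)
  J <- matrix(c(-1, -c_strength, c_strength, -1), 2, 2)
  p <- partition(1, 1, 0, 0)   # states (y, b): blanket is the single sensor
  sys <- make_system(J, gamma = sigma^2, partition = p)
  dens <- stationary_density(sys)
  field <- tidyr::expand_grid(y = grid, b = grid) |>
    dplyr::mutate(
      dy = -.data$y + c_strength * .data$b,
      db = -c_strength * .data$y - .data$b,
      radial = (.data$y * .data$dy + .data$b * .data$db) /
        pmax(sqrt(.data$y^2 + .data$b^2), .Machine$double.eps))
  moments <- conditional_moments(dens)
  cond <- tibble(b = grid,
                 flow_y = vapply(grid, function(bb)
                   marginal_flow_y(bb, sys, moments)[1], numeric(1)))
  list(flow_field = field, conditional_flow = cond, Q = dens$Q, J = J,
       eigenvalues = eigen(J, only.values = TRUE)$values, system = sys,
       density = dens)
}
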