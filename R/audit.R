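#' Markov-blanket residual of a precision matrix
#'
#' For a Gaussian stationary density the Markov blanket condition —
#' external and internal states conditionally independent given the
#' blanket — is exactly the vanishing of the precision block `H_yx`.
#' Returns the Frobenius norm of that block, absolutely and relative to
#' `||H||_F` (a scale-free diagnostic).
#'
#' @param H Symmetric precision matrix.
#' @param partition A [partition()].
#' @return Named list with `absolute` and `relative` residuals.
#' @export
markov_blanket_residual <- function(H, partition) {
  p <- as_partition(partition)
  r <- fnorm(blk(H, p, "y", "x"))
  list(absolute = r, relative = r / fnorm(H))
}

require_canonical_mask <- function(C, p) {
  for (zb in c("yx", "sx", "ay", "xy")) {
    if (fnorm(blk(C, p, substr(zb, 1, 1), substr(zb, 2, 2))) > 0) {
      abort(sprintf("second-order predictions require the canonical mask; C_%s != 0", zb),
            class = "fep_structure_error")
    }
  }
}

#' Second-order prediction for the precision block H_yx
#'
#' Under the canonical flow constraint and homogeneous noise, the leading
#' conditional coupling between external and internal states is second
#' order in the couplings:
#' `H_yx = -(sigma^{-2}/4) (C_ys C_xs' + C_ya C_xa') + O(C^3)`.
#'
#' @param C Coupling matrix satisfying the canonical mask.
#' @param sigma Scalar noise scale.
#' @param partition A [partition()].
#' @return The predicted `n_y x n_x` block.
#' @export
predicted_Hyx_second_order <- function(C, sigma, partition) {
  p <- as_partition(partition)
  require_canonical_mask(C, p)
  -(1 / (4 * sigma^2)) *
    (blk(C, p, "y", "s") %*% t(blk(C, p, "x", "s")) +
       blk(C, p, "y", "a") %*% t(blk(C, p, "x", "a")))
}

#' Residual norms of off-diagonal solenoidal blocks
#'
#' The strict decoupling assumption requires `Q` block-diagonal over
#' `(y, s, a, x)` (mode `"full_block_diagonal"`, checking the six upper
#' off-diagonal blocks `ys, ya, yx, sa, sx, ax`); the relaxed variant only
#' requires decoupling between autonomous `(a, x)` and non-autonomous
#' `(y, s)` states (mode `"autonomous_split"`, checking `ya, yx, sa, sx`).
#' Antisymmetry makes the lower blocks redundant.
#'
#' @param Q Antisymmetric solenoidal matrix.
#' @param partition A [partition()].
#' @param mode Decoupling mode.
#' @return Tibble with columns `block` and `residual` (Frobenius norms).
#' @export
solenoidal_block_residuals <- function(Q, partition,
                                       mode = c("full_block_diagonal",
                                                "autonomous_split")) {
  mode <- match.arg(mode)
  p <- as_partition(partition)
  blocks <- if (mode == "full_block_diagonal")
    c("ys", "ya", "yx", "sa", "sx", "ax") else c("ya", "yx", "sa", "sx")
  tibble(
    block = blocks,
    residual = vapply(blocks, function(bl)
      fnorm(blk(Q, p, substr(bl, 1, 1), substr(bl, 2, 2))), numeric(1)))
}

#' Second-order predictions for the off-diagonal solenoidal blocks
#'
#' Under the canonical mask and homogeneous noise the four blocks coupling
#' the environment to the autonomous side (and the sensor-motor blocks) are,
#' to second order in `C`:
#' \deqn{Q_{ya} = (s^2/4)(2 C_{ya} + C_{yy}C_{ya} + C_{ys}C_{sa} + C_{ya}C_{aa} - C_{sy}'C_{as}')}
#' \deqn{Q_{yx} = (s^2/4)(C_{ya}C_{ax} - C_{sy}'C_{xs}')}
#' \deqn{Q_{sa} = (s^2/4)(2(C_{sa} - C_{as}') + C_{sy}C_{ya} + C_{ss}C_{sa} + C_{sa}C_{aa} - C_{ss}'C_{as}' - C_{as}'C_{aa}' - C_{xs}'C_{ax}')}
#' \deqn{Q_{sx} = (s^2/4)(-2 C_{xs}' + C_{sa}C_{ax} - C_{ss}'C_{xs}' - C_{as}'C_{xa}' - C_{xs}'C_{xx}')}
#' with `s = sigma`. (The first-order parts reproduce the order-1 series
#' blocks `(sigma^2/2) C_ya`, `(sigma^2/2)(C_sa - C_as')`,
#' `-(sigma^2/2) C_xs'`.)
#'
#' @inheritParams predicted_Hyx_second_order
#' @return Named list of matrices `Q_ya`, `Q_yx`, `Q_sa`, `Q_sx`.
#' @export
predicted_Q_blocks_second_order <- function(C, sigma, partition) {
  p <- as_partition(partition)
  require_canonical_mask(C, p)
  g <- function(i, j) blk(C, p, i, j)
  s2 <- sigma^2
  list(
    Q_ya = (s2 / 4) * (2 * g("y", "a") + g("y", "y") %*% g("y", "a") +
                         g("y", "s") %*% g("s", "a") + g("y", "a") %*% g("a", "a") -
                         t(g("s", "y")) %*% t(g("a", "s"))),
    Q_yx = (s2 / 4) * (g("y", "a") %*% g("a", "x") -
                         t(g("s", "y")) %*% t(g("x", "s"))),
    Q_sa = (s2 / 4) * (2 * (g("s", "a") - t(g("a", "s"))) +
                         g("s", "y") %*% g("y", "a") + g("s", "s") %*% g("s", "a") +
                         g("s", "a") %*% g("a", "a") -
                         t(g("s", "s")) %*% t(g("a", "s")) -
                         t(g("a", "s")) %*% t(g("a", "a")) -
                         t(g("x", "s")) %*% t(g("a", "x"))),
    Q_sx = (s2 / 4) * (-2 * t(g("x", "s")) + g("s", "a") %*% g("a", "x") -
                         t(g("s", "s")) %*% t(g("x", "s")) -
                         t(g("a", "s")) %*% t(g("x", "a")) -
                         t(g("x", "s")) %*% t(g("x", "x"))))
}

#' Audit a system against the statistical requirements of the FEP
#'
#' Runs the full battery for one system: structure-mask check, exact NESS
#' solve, Markov-blanket residual on the precision, off-diagonal solenoidal
#' block residuals under the chosen decoupling mode, and — when the
#' canonical mask and homogeneous noise permit — the second-order
#' predictions for `H_yx` and the `Q` blocks. Verdicts are scale-free:
#' a residual passes when it is at most `tol` times the Frobenius norm of
#' the parent matrix (`H` or `Q`).
#'
#' @param system An `fep_system`.
#' @param tol Relative tolerance for pass/fail verdicts.
#' @param q_mode Solenoidal decoupling mode, see
#'   [solenoidal_block_residuals()].
#' @return Object of class `fep_audit`: list with the stationary density,
#'   `mb` (residuals), `q_blocks` (tibble with verdicts), `predictions`
#'   (or `NULL`), `structure_check`, `verdicts` and the tolerance.
#' @examples
#' sys <- generate_random_system("canonical", partition(2, 1, 1, 2), seed = 7)
#' aud <- audit_system(sys)
#' glance(aud)
#' @export
audit_system <- function(system, tol = 1e-8,
                         q_mode = c("full_block_diagonal", "autonomous_split")) {
  q_mode <- match.arg(q_mode)
  sc <- check_structure(system)
  dens <- stationary_density(system)
  p <- system$partition
  mb <- markov_blanket_residual(dens$H, p)
  qb <- solenoidal_block_residuals(dens$Q, p, q_mode)
  qnorm_ <- fnorm(dens$Q)
  qb$relative <- if (qnorm_ > 0) qb$residual / qnorm_ else 0
  qb$pass <- qb$residual <= tol * max(qnorm_, .Machine$double.xmin)
  predictions <- NULL
  canonical_ok <- tryCatch({require_canonical_mask(system$C, p); TRUE},
                           error = function(e) FALSE)
  if (canonical_ok && !is.na(system$sigma) && system$sigma > 0) {
    predictions <- list(
      Hyx_second_order = predicted_Hyx_second_order(system$C, system$sigma, p),
      Q_blocks_second_order = predicted_Q_blocks_second_order(system$C, system$sigma, p))
  }
  structure(
    list(system = system, density = dens, mb = mb, q_blocks = qb,
         q_mode = q_mode, predictions = predictions, structure_check = sc,
         tol = tol,
         verdicts = list(
           structure = isTRUE(attr(sc, "verdict")),
           markov_blanket = mb$relative <= tol,
           solenoidal_decoupling = all(qb$pass))),
    class = "fep_audit")
}

#' @export
print.fep_audit <- function(x, ...) {
  v <- x$verdicts
  mark <- function(b) if (b) "pass" else "FAIL"
  cat(sprintf("<fep_audit> %s system, n = %d, tol = %g (%s)\n",
              x$system$structure, x$system$partition$n, x$tol, x$q_mode))
  cat(sprintf("  structure mask:        %s\n", mark(v$structure)))
  cat(sprintf("  Markov blanket:        %s  (|H_yx|/|H| = %.3g)\n",
              mark(v$markov_blanket), x$mb$relative))
  cat(sprintf("  solenoidal decoupling: %s  (max block |Q_ij| = %.3g)\n",
              mark(v$solenoidal_decoupling), max(x$q_blocks$residual, 0)))
  invisible(x)
}

#' @describeIn audit_system Long tibble of all audit residuals.
#' @param x An `fep_audit`.
#' @param ... Unused.
#' @export
tidy.fep_audit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = c("mb_absolute", "mb_relative"),
           value = c(x$mb$absolute, x$mb$relative)),
    tibble(metric = paste0("q_", x$q_blocks$block), value = x$q_blocks$residual),
    tibble(metric = paste0("ness_", names(x$density$residuals)),
           value = unlist(x$density$residuals, use.names = FALSE)))
}

#' @describeIn audit_system One-row summary with verdicts.
#' @export
glance.fep_audit <- function(x, ...) {
  tibble(
    structure = x$system$structure, n = x$system$partition$n,
    tol = x$tol, q_mode = x$q_mode,
    mb_relative = x$mb$relative,
    q_offblock_max = max(x$q_blocks$residual, 0),
    structure_pass = x$verdicts$structure,
    mb_pass = x$verdicts$markov_blanket,
    q_pass = x$verdicts$solenoidal_decoupling)
}

#' Residuals of generated systems across a grid of coupling strengths
#'
#' Generates matched-seed systems (same Rademacher sign pattern at every
#' `epsilon`) for each `(epsilon, seed)` pair, audits them, and returns all
#' residuals in long format — the raw material for the scaling-law fits
#' (Markov-blanket residual exponent approximately 2 for canonical systems,
#' 3 for circular and symmetric-chain structures).
#'
#' @param structure Structure label.
#' @param partition A [partition()].
#' @param sigma Noise scale.
#' @param epsilons Numeric vector of coupling magnitudes.
#' @param seeds Integer vector of generator seeds.
#' @param q_mode Decoupling mode for the `Q` residuals.
#' @param ... Passed to [generate_random_system()].
#' @return Tibble `(structure, epsilon, seed, metric, value)`.
#' @export
epsilon_sweep <- function(structure, partition, sigma, epsilons, seeds,
                          q_mode = "full_block_diagonal", ...) {
  p <- as_partition(partition)
  grid <- tidyr::expand_grid(epsilon = epsilons, seed = seeds)
  purrr::pmap_dfr(grid, function(epsilon, seed) {
    sys <- generate_random_system(structure, p, epsilon = epsilon,
                                  sigma = sigma, seed = seed, ...)
    if (epsilon == 0) {
      # uncoupled limit: every residual is exactly zero, no solve needed
      aud_metrics <- tibble(
        metric = c("mb_absolute", "mb_relative", "q_ys", "q_ya", "q_yx",
                   "q_sa", "q_sx", "q_ax"),
        value = 0)
    } else {
      aud_metrics <- tidy(audit_system(sys, q_mode = q_mode)) |>
        dplyr::filter(!startsWith(.data$metric, "ness_"))
    }
    dplyr::mutate(aud_metrics, structure = structure, epsilon = epsilon,
                  seed = seed, .before = 1)
  })
}

#' Fit log-log scaling exponents from a sweep table
#'
#' For each metric, takes the median residual over seeds at each `epsilon`
#' and fits the slope of `log(median)` on `log(epsilon)` — the empirical
#' order of the residual in the coupling strength.
#'
#' @param sweep A tibble from [epsilon_sweep()].
#' @return Tibble `(structure, metric, slope, n_epsilon)`.
#' @export
sweep_exponents <- function(sweep) {
  sweep |>
    dplyr::filter(.data$epsilon > 0, .data$value > 0) |>
    dplyr::group_by(.data$structure, .data$metric, .data$epsilon) |>
    dplyr::summarise(med = median(.data$value), .groups = "drop_last") |>
    dplyr::summarise(
      slope = if (dplyr::n() >= 2)
        coef(lm(log(med) ~ log(epsilon)))[[2]] else NA_real_,
      n_epsilon = dplyr::n(), .groups = "drop")
}
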