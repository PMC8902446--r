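#' Construct a partitioned linear Langevin system
#'
#' Defines the generative process `dz/dt = J (z - rho) + omega_t`, where
#' `omega_t` is Gaussian white noise with covariance `2 Gamma` (`Gamma`
#' diagonal, non-negative) and the states are partitioned as
#' `z = (y, s, a, x)`. The drift must be Hurwitz (all eigenvalues with
#' strictly negative real part) so that a stationary density exists; the
#' coupling matrix is `C = J + I`.
#'
#' @param J Real `n x n` drift matrix.
#' @param rho Length-`n` set-point vector (stationary mean); defaults to 0.
#' @param gamma Noise matrix `Gamma`: a diagonal matrix, a length-`n` vector
#'   of diagonal entries, or a single scalar `v` meaning `Gamma = v * I`.
#' @param partition A [partition()] object (or a length-4 count vector).
#' @param structure Claimed structure label; validated against `C` unless
#'   `"unconstrained"`.
#' @param seed Optional integer recorded for provenance (not used here).
#' @param loop_direction Circular-loop orientation, see [structure_mask()].
#' @return An object of class `fep_system`: list with elements `J`, `C`,
#'   `rho`, `gamma` (diagonal entries), `sigma` (scalar noise scale if
#'   `Gamma` is homogeneous, otherwise `NA`), `partition`, `structure`,
#'   `seed`, `hurwitz_margin` (largest real part of the spectrum of `J`,
#'   negative for valid systems) and `loop_direction`.
#' @seealso [generate_random_system()], [check_structure()]
#' @examples
#' p <- partition(1, 1, 1, 1)
#' sys <- make_system(-diag(4), gamma = 0.01, partition = p)
#' sys$hurwitz_margin   # -1
#' @export
make_system <- function(J, rho = NULL, gamma = 1, partition,
                        structure = "unconstrained", seed = NULL,
                        loop_direction = "forward") {
  p <- as_partition(partition)
  J <- as.matrix(J)
  if (!is.numeric(J) || nrow(J) != p$n || ncol(J) != p$n) {
    abort(sprintf("J must be a %d x %d numeric matrix for this partition", p$n, p$n),
          class = "fep_dimension_error")
  }
  if (is.null(rho)) rho <- rep(0, p$n)
  rho <- as.numeric(rho)
  if (length(rho) != p$n) {
    abort("rho must have the system dimension", class = "fep_dimension_error")
  }
  if (is.matrix(gamma)) {
    if (any(dim(gamma) != p$n)) {
      abort("gamma matrix must be n x n", class = "fep_dimension_error")
    }
    if (max(abs(gamma - diag(diag(gamma), p$n))) > 0) {
      abort("gamma must be diagonal", class = "fep_dimension_error")
    }
    gamma <- diag(gamma)
  } else if (length(gamma) == 1) {
    gamma <- rep(as.numeric(gamma), p$n)
  }
  gamma <- as.numeric(gamma)
  if (length(gamma) != p$n || any(gamma < 0)) {
    abort("gamma diagonal must be length n with non-negative entries",
          class = "fep_dimension_error")
  }
  if (!structure %in% structure_labels) {
    abort(sprintf("unknown structure label '%s'", structure),
          class = "fep_structure_error")
  }
  margin <- max(Re(eigen(J, only.values = TRUE)$values))
  if (margin >= 0) {
    abort(sprintf("J is not Hurwitz: largest real part of spectrum is %.3g", margin),
          class = "fep_stability_error")
  }
  sys <- structure(
    list(J = unname(J), C = unname(J) + diag(p$n), rho = rho, gamma = gamma,
         sigma = if (length(unique(gamma)) == 1) sqrt(gamma[1]) else NA_real_,
         partition = p, structure = structure, seed = seed,
         hurwitz_margin = margin, loop_direction = loop_direction),
    class = "fep_system")
  if (structure != "unconstrained" && !structure_ok(sys, structure)) {
    abort(sprintf("coupling matrix violates the '%s' structure mask", structure),
          class = "fep_structure_error")
  }
  sys
}

#' @export
print.fep_system <- function(x, ...) {
  cat(sprintf("<fep_system> %s, partition %s, n = %d\n",
              x$structure, format(x$partition), x$partition$n))
  cat(sprintf("  noise: %s; Hurwitz margin %.4g; seed %s\n",
              if (!is.na(x$sigma)) sprintf("homogeneous sigma = %g", x$sigma)
              else "heterogeneous diagonal",
              x$hurwitz_margin,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

gamma_matrix <- function(system) diag(system$gamma, system$partition$n)

#' Generate a random weakly-coupled system under a structure mask
#'
#' Draws a coupling matrix `C` whose mask-allowed entries are independent
#' Rademacher signs times `epsilon` (i.e. exactly `+epsilon` or `-epsilon`,
#' including within-block diagonals), mirrors the symmetric pairs of the
#' mask, zeroes the forbidden blocks, and returns the system with
#' `J = -I + C`, homogeneous noise `Gamma = sigma^2 I` and `rho = 0`.
#' The full sign pattern is drawn in one pass from `seed`, so the same seed
#' yields the same pattern at every `epsilon` (matched-seed sweeps isolate
#' `epsilon`-scaling from sign-pattern noise). If the draw is not Hurwitz it
#' is resampled, up to `max_retries` times.
#'
#' @param structure Structure label, see [structure_mask()].
#' @param partition A [partition()].
#' @param epsilon Coupling magnitude (entries of `C` are `0` or `±epsilon`).
#' @param sigma Noise scale; `Gamma = sigma^2 I`.
#' @param seed Integer seed; fully determines the output.
#' @param max_retries Maximum Hurwitz resampling attempts.
#' @param zero_yb If `TRUE`, additionally zero the `C_ys` and `C_ya` blocks
#'   after masking (an agent that observes without being acted back upon is
#'   obtained with the transposed blocks present; this switch removes any
#'   direct blanket influence on the environment block).
#' @param loop_direction Circular-loop orientation.
#' @return An `fep_system`.
#' @examples
#' sys <- generate_random_system("symmetric_chain", partition(2, 1, 1, 2),
#'                               epsilon = 0.1, sigma = 0.1, seed = 42)
#' unique(as.vector(sys$C))      # entries in {-0.1, 0, 0.1} plus the -1 shift in J
#' @export
generate_random_system <- function(structure, partition, epsilon = 0.1,
                                   sigma = 0.1, seed = NULL, max_retries = 100,
                                   zero_yb = FALSE,
                                   loop_direction = c("forward", "reverse")) {
  loop_direction <- match.arg(loop_direction)
  p <- as_partition(partition)
  if (epsilon < 0 || sigma < 0) {
    abort("epsilon and sigma must be non-negative", class = "fep_dimension_error")
  }
  mask <- structure_mask(structure, loop_direction)
  draw_C <- function() {
    signs <- matrix(sample(c(-1, 1), p$n^2, replace = TRUE), p$n, p$n)
    C <- epsilon * signs
    for (zb in mask$zero_blocks) {
      blk(C, p, substr(zb, 1, 1), substr(zb, 2, 2)) <- 0
    }
    for (sp in mask$symmetric_pairs) {
      primary <- blk(C, p, substr(sp[1], 1, 1), substr(sp[1], 2, 2))
      blk(C, p, substr(sp[2], 1, 1), substr(sp[2], 2, 2)) <- t(primary)
    }
    if (zero_yb) {
      blk(C, p, "y", "s") <- 0
      blk(C, p, "y", "a") <- 0
      # keep symmetric pairs consistent if the mask mirrored into them
      for (sp in mask$symmetric_pairs) {
        if (sp[1] %in% c("ys", "ya")) {
          blk(C, p, substr(sp[2], 1, 1), substr(sp[2], 2, 2)) <- 0
        }
      }
    }
    C
  }
  run <- function() {
    for (k in seq_len(max_retries + 1)) {
      C <- draw_C()
      J <- -diag(p$n) + C
      if (max(Re(eigen(J, only.values = TRUE)$values)) < 0) {
        attr(J, "retries") <- k - 1L
        return(J)
      }
    }
    abort(sprintf("could not draw a Hurwitz J in %d retries (epsilon = %g too large?)",
                  max_retries, epsilon),
          class = "fep_generation_error")
  }
  J <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  retries <- attr(J, "retries")
  attr(J, "retries") <- NULL
  sys <- make_system(J, rho = rep(0, p$n), gamma = sigma^2, partition = p,
                     structure = "unconstrained",
                     seed = seed, loop_direction = loop_direction)
  # zeroing C_yb can break a symmetric pair; keep the label only if it still holds
  sys$structure <- if (structure_ok(sys, structure)) structure else "unconstrained"
  sys$generating_structure <- structure
  sys$retries <- retries
  sys$epsilon <- epsilon
  sys$zero_yb <- zero_yb
  sys
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Drift field of a system
#'
#' Evaluates `f(z) = J (z - rho)` for one state or the columns of a matrix.
#' @param system An `fep_system`.
#' @param z State vector or `n x m` matrix of states.
#' @return Drift vector/matrix of the same shape.
#' @export
drift <- function(system, z) {
  if (is.matrix(z)) system$J %*% (z - system$rho) else
    as.numeric(system$J %*% (z - system$rho))
}
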