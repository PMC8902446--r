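#' Sensorimotor structure masks for the coupling matrix
#'
#' A structure label constrains which between-block entries of the coupling
#' matrix `C` (where the drift is `J = -I + C`) may be non-zero, and which
#' block pairs are forced to be mutual transposes:
#'
#' * `canonical` — the perception-action interface: external and sensory
#'   dynamics do not read internal states, active and internal dynamics do
#'   not read external states. Zero blocks: `C_yx`, `C_sx`, `C_ay`, `C_xy`.
#' * `circular` — a unidirectional cycle `y -> s -> x -> a -> y`: the only
#'   between-block entries allowed are `C_sy`, `C_xs`, `C_ax`, `C_ya`
#'   (within-block entries are always free). `loop_direction = "reverse"`
#'   selects the opposite orientation (`C_ys`, `C_sx`, `C_xa`, `C_ay`).
#' * `symmetric_chain` — the canonical zeros plus `C_ya = 0`, `C_xs = 0`,
#'   with all remaining between-block couplings symmetric:
#'   `C_ys = C_sy'`, `C_sa = C_as'`, `C_ax = C_xa'`. Asymmetry (hence any
#'   solenoidal tendency) is confined to within-block entries.
#' * `unconstrained` — no constraints.
#'
#' @param structure One of `"canonical"`, `"circular"`, `"symmetric_chain"`,
#'   `"unconstrained"`.
#' @param loop_direction Orientation of the circular loop; ignored for other
#'   structures.
#' @return A list with `zero_blocks` (character pairs "ij" forced to zero in
#'   `C`) and `symmetric_pairs` (pairs with `C_ij = C_ji'` enforced; the
#'   first label is the primary draw, the second is mirrored).
#' @export
structure_mask <- function(structure, loop_direction = c("forward", "reverse")) {
  loop_direction <- match.arg(loop_direction)
  off <- apply(expand.grid(BLOCKS, BLOCKS), 1, paste0, collapse = "")
  off <- off[substr(off, 1, 1) != substr(off, 2, 2)]
  switch(structure,
    unconstrained = list(zero_blocks = character(0), symmetric_pairs = list()),
    canonical = list(zero_blocks = c("yx", "sx", "ay", "xy"),
                     symmetric_pairs = list()),
    circular = {
      allowed <- if (loop_direction == "forward") c("sy", "xs", "ax", "ya")
                 else c("ys", "sx", "xa", "ay")
      list(zero_blocks = setdiff(off, allowed), symmetric_pairs = list())
    },
    symmetric_chain = list(
      zero_blocks = c("yx", "sx", "ay", "xy", "ya", "xs"),
      symmetric_pairs = list(c("ys", "sy"), c("sa", "as"), c("ax", "xa"))
    ),
    abort(sprintf("unknown structure label '%s'", structure),
          class = "fep_structure_error")
  )
}

structure_labels <- c("canonical", "circular", "symmetric_chain", "unconstrained")

#' Check a system's coupling matrix against a structure mask
#'
#' Computes, for every between-block constraint of the requested structure,
#' the Frobenius norm of the violating part of `C = J + I`: the norm of each
#' block required to vanish, and `||C_ij - C_ji'||` for each symmetric pair.
#'
#' @param system A [make_system()] object.
#' @param structure Structure label to check against; defaults to the label
#'   the system claims.
#' @param tol Non-negative tolerance on each residual.
#' @return A tibble with columns `constraint` (`"zero"` or `"symmetric"`),
#'   `block`, and `residual`, with attributes `verdict` (logical: all
#'   residuals `<= tol`) and `tol`.
#' @examples
#' sys <- generate_random_system("canonical", partition(2, 1, 1, 2), seed = 1)
#' check_structure(sys)                      # all residuals exactly 0
#' @export
check_structure <- function(system, structure = system$structure, tol = 0) {
  stopifnot(inherits(system, "fep_system"))
  ld <- system$loop_direction %||% "forward"
  mask <- structure_mask(structure, ld)
  p <- system$partition
  C <- system$C
  rows <- list()
  for (zb in mask$zero_blocks) {
    i <- substr(zb, 1, 1); j <- substr(zb, 2, 2)
    rows[[length(rows) + 1]] <- tibble(
      constraint = "zero", block = zb, residual = fnorm(blk(C, p, i, j)))
  }
  for (sp in mask$symmetric_pairs) {
    rows[[length(rows) + 1]] <- tibble(
      constraint = "symmetric", block = paste0(sp[1], "/", sp[2]),
      residual = fnorm(blk(C, p, substr(sp[1], 1, 1), substr(sp[1], 2, 2)) -
                         t(blk(C, p, substr(sp[2], 1, 1), substr(sp[2], 2, 2)))))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(constraint = character(0), block = character(0), residual = numeric(0))
  attr(out, "verdict") <- all(out$residual <= tol)
  attr(out, "tol") <- tol
  out
}

structure_ok <- function(system, structure = system$structure, tol = 1e-12) {
  isTRUE(attr(check_structure(system, structure, tol), "verdict"))
}
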