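#' State-space partition into external, sensory, active and internal blocks
#'
#' The systems studied here carry a fixed four-way partition of the state
#' vector `z = (y, s, a, x)`: external states `y`, sensory states `s`, active
#' states `a` and internal states `x`. The blanket `b = (s, a)` concatenates
#' the sensory and active blocks. All block indexing in the package derives
#' from this object, and the state ordering `(y, s, a, x)` is fixed.
#'
#' @param n_y,n_s,n_a,n_x Non-negative integer counts of external, sensory,
#'   active and internal states.
#' @return An object of class `fep_partition`: a list with the four counts,
#'   the total dimension `n`, the blanket size `n_b = n_s + n_a`, and an
#'   index list `idx` with integer positions of each block (including `b`).
#' @examples
#' p <- partition(2, 1, 1, 2)
#' p$idx$b   # blanket indices: 3 4
#' @export
partition <- function(n_y, n_s, n_a, n_x) {
  counts <- c(y = n_y, s = n_s, a = n_a, x = n_x)
  if (any(counts != round(counts)) || any(counts < 0)) {
    abort("partition counts must be non-negative integers", class = "fep_dimension_error")
  }
  counts <- setNames(as.integer(round(counts)), names(counts))
  n <- sum(counts)
  if (n < 2) {
    abort("partition must contain at least two states in total", class = "fep_dimension_error")
  }
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  idx <- lapply(seq_along(counts), function(i) {
    if (counts[i] == 0L) integer(0) else seq.int(starts[i], ends[i])
  })
  names(idx) <- names(counts)
  idx$b <- c(idx$s, idx$a)
  structure(
    list(n_y = counts[["y"]], n_s = counts[["s"]], n_a = counts[["a"]],
         n_x = counts[["x"]], n = n, n_b = counts[["s"]] + counts[["a"]],
         idx = idx),
    class = "fep_partition"
  )
}

#' @export
print.fep_partition <- function(x, ...) {
  cat(sprintf("<fep_partition> n = %d  (y: %d, s: %d, a: %d, x: %d; blanket: %d)\n",
              x$n, x$n_y, x$n_s, x$n_a, x$n_x, x$n_b))
  invisible(x)
}

#' @export
format.fep_partition <- function(x, ...) {
  sprintf("(%d,%d,%d,%d)", x$n_y, x$n_s, x$n_a, x$n_x)
}

as_partition <- function(p) {
  if (inherits(p, "fep_partition")) return(p)
  if (is.numeric(p) && length(p) == 4) return(partition(p[1], p[2], p[3], p[4]))
  if (is.list(p) && all(c("n_y", "n_s", "n_a", "n_x") %in% names(p))) {
    return(partition(p$n_y, p$n_s, p$n_a, p$n_x))
  }
  abort("cannot interpret `partition`; use partition(n_y, n_s, n_a, n_x)",
        class = "fep_dimension_error")
}

# Extract block M[i, j] for block labels i, j in {y, s, a, x, b}.
blk <- function(M, p, i, j) {
  M[p$idx[[i]], p$idx[[j]], drop = FALSE]
}

# Assign into a block of M; used by generators and predictions.
`blk<-` <- function(M, p, i, j, value) {
  M[p$idx[[i]], p$idx[[j]]] <- value
  M
}
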