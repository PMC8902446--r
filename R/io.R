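#' Read and write systems as JSON
#'
#' A system is serialized as a flat JSON document with fields `version`,
#' `structure`, `seed`, `partition` (object with `ny`, `ns`, `na`, `nx`),
#' `J` (row-major nested arrays), `rho` and `gamma_diagonal`. Unknown extra
#' fields are preserved on read (attached as the `extra` element) and
#' ignored otherwise, for forward compatibility. `write_system()` followed
#' by `read_system()` reproduces the system up to floating-point round-trip
#' (exactly, since full precision is written).
#'
#' @param system An `fep_system`.
#' @param path File path.
#' @return `read_system()` returns an `fep_system`; `write_system()` returns
#'   `path` invisibly.
#' @export
write_system <- function(system, path) {
  stopifnot(inherits(system, "fep_system"))
  p <- system$partition
  doc <- list(
    version = "1",
    structure = system$structure,
    seed = system$seed,
    loop_direction = system$loop_direction,
    partition = list(ny = p$n_y, ns = p$n_s, na = p$n_a, nx = p$n_x),
    J = apply(system$J, 1, as.numeric, simplify = FALSE),
    rho = system$rho,
    gamma_diagonal = system$gamma
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_system
#' @export
read_system <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort(
                    sprintf("malformed system JSON: %s", conditionMessage(e)),
                    class = "fep_schema_error"))
  required <- c("structure", "partition", "J", "rho", "gamma_diagonal")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    abort(sprintf("system JSON missing field(s): %s", paste(missing, collapse = ", ")),
          class = "fep_schema_error")
  }
  pd <- doc$partition
  if (!all(c("ny", "ns", "na", "nx") %in% names(pd))) {
    abort("partition object must contain ny, ns, na, nx", class = "fep_schema_error")
  }
  p <- partition(pd$ny, pd$ns, pd$na, pd$nx)
  rows <- lapply(doc$J, function(r) as.numeric(unlist(r)))
  if (length(rows) != p$n || any(lengths(rows) != p$n)) {
    abort("J has a shape inconsistent with the partition", class = "fep_schema_error")
  }
  J <- do.call(rbind, rows)
  sys <- make_system(J,
                     rho = as.numeric(unlist(doc$rho)),
                     gamma = as.numeric(unlist(doc$gamma_diagonal)),
                     partition = p,
                     structure = doc$structure %||% "unconstrained",
                     seed = doc$seed,
                     loop_direction = doc$loop_direction %||% "forward")
  extra <- doc[setdiff(names(doc), c(required, "version", "seed", "loop_direction"))]
  if (length(extra)) sys$extra <- extra
  sys
}
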