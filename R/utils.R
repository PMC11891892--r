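# Condition constructors and small shared helpers.

intergen_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "intergen_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

intergen_warn <- function(message) {
  warning(message, call. = FALSE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Sign of the permutation that sorts `vals` ascending (ties not allowed).
# Used for tetrahedral parity bookkeeping: an odd reordering of the four
# neighbour references flips the MDL parity.
perm_sign <- function(perm) {
  n <- length(perm)
  inv <- 0L
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      inv <- inv + sum(perm[(i + 1L):n] < perm[i])
    }
  }
  if (inv %% 2L == 0L) 1L else -1L
}

flip_parity <- function(p) {
  if (p == 0L) 0L else if (p == 1L) 2L else 1L
}

# Reorder a parity reference list. `vals` holds, in the OLD reference order,
# the sort keys of the new neighbour identities (Inf = implicit H, which by
# MDL convention ranks last). Returns the adjusted parity.
reorder_parity <- function(parity, vals) {
  if (parity == 0L) return(0L)
  if (anyNA(vals)) return(0L)
  if (sum(!is.finite(vals)) > 1L) return(0L)      # >1 implicit H: not a stereocentre
  if (anyDuplicated(vals[is.finite(vals)])) return(0L)
  if (perm_sign(order(vals)) < 0L) flip_parity(parity) else parity
}
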