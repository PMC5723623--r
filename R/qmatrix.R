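#' Anagenetic rate matrix for one epoch
#'
#' Builds the instantaneous rate matrix over the range state space for a
#' single epoch's multiplier matrix. Range expansion into area `a` happens
#' at rate `d * sum(m[b, a])` over occupied source areas `b` (blocked when
#' the expanded range would exceed `max_range_size`); contraction (local
#' extinction) removes any occupied area at rate `e`. The null range is
#' reachable from singletons and absorbing. Rows sum to zero.
#'
#' @param space A `range_state_space`.
#' @param d Dispersal rate (range-expansion events per Ma per source area).
#' @param e Extinction rate (per Ma per occupied area).
#' @param m Multiplier matrix over `space$areas` (rows = source).
#' @return Dense square rate matrix, one row/column per state.
#' @export
build_q_matrix <- function(space, d, e, m) {
  n <- length(space$areas)
  if (!all(dim(m) == c(n, n))) abort("multiplier matrix does not match the area set")
  S <- length(space$mask)
  Q <- matrix(0, S, S)
  for (i in seq_len(S)) {
    mask <- space$mask[i]
    if (mask == 0L) next # null range is absorbing
    members <- mask_areas(mask, n)
    if (length(members) < space$max_range_size) {
      for (a in setdiff(seq_len(n), members)) {
        k <- space$index_of[bitwOr(mask, bitwShiftL(1L, a - 1L)) + 1L]
        if (!is.na(k)) Q[i, k] <- d * sum(m[members, a])
      }
    }
    for (a in members) {
      k <- space$index_of[bitwAnd(mask, bitwNot(bitwShiftL(1L, a - 1L))) + 1L]
      Q[i, k] <- Q[i, k] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}
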