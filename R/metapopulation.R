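#' Draw migrating hosts
#'
#' For each deme j, the number of migrants z_j is Binomial(n_j, q) and z_j
#' distinct host slots are chosen uniformly without replacement within the
#' deme.
#'
#' @param metapop a [Metapopulation-class].
#' @return list with `z` (per-deme migrant counts) and `slots` (integer host
#'   slot indices of all selected migrants).
#' @export
drawMigrants <- function(metapop) {
  stopifnot(is(metapop, "Metapopulation"))
  nd <- 2L^metapop@k
  slots <- integer(0)
  z <- integer(nd)
  for (d in seq_len(nd)) {
    rows <- which(metapop@demeId == d)
    z[d] <- rbinom(1L, size = length(rows), prob = metapop@q)
    if (z[d] > 0L)
      slots <- c(slots, rows[sample.int(length(rows), z[d])])
  }
  list(z = z, slots = slots)
}

#' Migrate hosts by shuffle-reassignment
#'
#' All selected migrants are pooled and reassigned to the union of vacated
#' slots by a single uniform permutation. Deme sizes are preserved; the host
#' multiset over the whole metapopulation is unchanged; a migrant may land
#' back in its origin deme.
#'
#' @param metapop a [Metapopulation-class].
#' @return the metapopulation with migrants reassigned.
#' @export
migrate <- function(metapop) {
  stopifnot(is(metapop, "Metapopulation"))
  mig <- drawMigrants(metapop)
  slots <- mig$slots
  if (length(slots) < 2L) return(metapop)
  perm <- slots[sample.int(length(slots))]
  metapop@counts[slots, ] <- metapop@counts[perm, , drop = FALSE]
  metapop@ageSteps[slots] <- metapop@ageSteps[perm]
  metapop
}
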