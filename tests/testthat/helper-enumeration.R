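# Exhaustive enumeration of the reachable bond states of a 3-monomer BFM
# chain, modulo translation.  A state is the bond pair (b1, b2); single-site
# moves of monomer 1/2/3 map to (b1 - e, b2), (b1 + e, b2 - e), (b1, b2 + e).
# A state is admissible when both bonds are in the bond set and the end
# monomers' 2x2x2 cubes are disjoint (some |component| of b1 + b2 >= 2).
# The state key matches the engine's compact bond encoding.

bond_code <- function(b) (b[1] + 3) * 49 + (b[2] + 3) * 7 + (b[3] + 3)

state_key <- function(b1, b2) bond_code(b1) + 343 * bond_code(b2)

enumerate_n3_states <- function() {
  bonds <- dl_bond_vectors()
  bond_set <- new.env(hash = TRUE)
  for (k in seq_len(nrow(bonds)))
    assign(as.character(bond_code(bonds[k, ])), TRUE, envir = bond_set)
  in_bond_set <- function(b) {
    if (any(abs(b) > 3)) return(FALSE)
    exists(as.character(bond_code(b)), envir = bond_set)
  }
  admissible <- function(b1, b2) {
    in_bond_set(b1) && in_bond_set(b2) && any(abs(b1 + b2) >= 2)
  }
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  start <- list(b1 = c(2L, 0L, 0L), b2 = c(2L, 0L, 0L))
  seen <- new.env(hash = TRUE)
  queue <- list(start)
  assign(as.character(state_key(start$b1, start$b2)), TRUE, envir = seen)
  while (length(queue) > 0L) {
    st <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in seq_len(6)) {
      e <- dirs[d, ]
      nbrs <- list(list(b1 = st$b1 - e, b2 = st$b2),
                   list(b1 = st$b1 + e, b2 = st$b2 - e),
                   list(b1 = st$b1, b2 = st$b2 + e))
      for (nb in nbrs) {
        if (!admissible(nb$b1, nb$b2)) next
        k <- as.character(state_key(nb$b1, nb$b2))
        if (!exists(k, envir = seen)) {
          assign(k, TRUE, envir = seen)
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  sort(as.numeric(ls(envir = seen)))
}
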