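#' Allowed BFM bond vectors
#'
#' Returns the full three-dimensional Bond Fluctuation Model bond family:
#' all permutations and sign changes of the base vectors (2,0,0), (2,1,0),
#' (2,1,1), (2,2,1), (3,0,0) and (3,1,0).  The set has 108 members with
#' lengths in \{2, sqrt(5), sqrt(6), 3, sqrt(10)\}; together with
#' single-site moves it guarantees excluded volume and preservation of the
#' chain topology.
#'
#' @return An integer matrix with 108 rows and columns `dx`, `dy`, `dz`.
#' @export
#' @examples
#' b <- dl_bond_vectors()
#' nrow(b)            # 108
#' sort(unique(rowSums(b^2)))  # 4 5 6 9 10
dl_bond_vectors <- function() {
  b <- cpp_bond_vectors()
  colnames(b) <- c("dx", "dy", "dz")
  b
}

#' Test whether a displacement is an allowed bond vector
#'
#' @param d Integer vector of length 3.
#' @return `TRUE` if `d` belongs to the BFM bond set.
#' @export
dl_is_bond_vector <- function(d) {
  cpp_is_bond_vector(as.integer(d))
}

#' Lattice configuration
#'
#' The simulation lattice is periodic with edge `box_edge`.  Coordinates are
#' stored unwrapped; wrapping is applied only inside the excluded-volume
#' occupancy index, so the polymer is never spatially confined.  The default
#' box edge (chosen by [dl_init_chain()]) is four times the contour length of
#' the initial straight rod, which makes collisions across the periodic
#' image geometrically impossible.
#'
#' @param box_edge Even integer lattice edge length, at least 8.
#' @return A list of class `dl_lattice` with fields `box_edge` and
#'   `bond_vectors`.
#' @export
dl_lattice_config <- function(box_edge) {
  box_edge <- as.integer(box_edge)
  if (length(box_edge) != 1L || is.na(box_edge) || box_edge < 8L)
    stop("box_edge must be a single integer >= 8")
  if (box_edge %% 2L != 0L)
    stop("box_edge must be even")
  if (box_edge > 2^20)
    stop("box_edge must be at most 2^20")
  structure(list(box_edge = box_edge, bond_vectors = dl_bond_vectors()),
            class = "dl_lattice")
}

dl_default_box <- function(n_monomers) {
  # at least 4 x the rod contour length, rounded up to a power of two
  # (power-of-two edges let the occupancy index wrap with a bitmask)
  e <- 8L * (as.integer(n_monomers) - 1L)
  as.integer(2^ceiling(log2(max(64L, e))))
}

#' Construct a conformation object
#'
#' A conformation bundles the unwrapped integer monomer positions, the
#' active cross-link set and the sweep counter.  Use `validate = TRUE`
#' (the default) to assert the lattice invariants: all consecutive
#' displacements in the bond set, no overlap of the 2x2x2 monomer cubes and
#' all cross-link displacements in the bond set.
#'
#' @param positions Integer matrix, one row per monomer, columns x, y, z.
#' @param links Integer matrix with columns `i`, `j`, `expiry` (1-based
#'   monomer indices, `i < j`); may have zero rows.
#' @param sweep Sweep counter (non-negative).
#' @param box Periodic box edge.
#' @param validate Check invariants on construction?
#' @return An object of class `dl_conformation`.
#' @export
dl_conformation <- function(positions, links = NULL, sweep = 0, box = NULL,
                            validate = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "integer"
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  if (is.null(links)) links <- matrix(integer(0), 0L, 3L)
  links <- as.matrix(links)
  storage.mode(links) <- "integer"
  if (ncol(links) != 3L) stop("links must have columns i, j, expiry")
  colnames(links) <- c("i", "j", "expiry")
  if (is.null(box)) box <- dl_default_box(nrow(positions))
  conf <- structure(
    list(positions = positions, links = links,
         sweep = as.numeric(sweep), box = as.integer(box)),
    class = "dl_conformation")
  if (validate) dl_validate(conf)
  conf
}

#' @export
print.dl_conformation <- function(x, ...) {
  cat(sprintf("<dl_conformation> N = %d, %d active cross-link(s), sweep %s, box %d\n",
              nrow(x$positions), nrow(x$links),
              format(x$sweep, big.mark = ","), x$box))
  invisible(x)
}

#' Validate a conformation
#'
#' Asserts the full set of lattice invariants (bond vectors, excluded
#' volume, cross-link legality).  Called after every mutating operation in
#' the test suite.
#'
#' @param conf A `dl_conformation`.
#' @param cutoff Optional genomic cutoff; when positive, cross-link
#'   separations are also checked against it.
#' @return Invisibly `TRUE`; stops with all detected problems otherwise.
#' @export
dl_validate <- function(conf, cutoff = 0L) {
  stopifnot(inherits(conf, "dl_conformation"))
  msg <- cpp_validate(conf$positions, conf$links, conf$box, as.integer(cutoff))
  if (length(msg) > 0L)
    stop("invalid conformation:\n  ", paste(msg, collapse = "\n  "))
  invisible(TRUE)
}

#' Excluded-volume check for a proposed monomer position
#'
#' Tests whether moving monomer `index` to `proposed` would keep all
#' 2x2x2 occupied-site cubes disjoint (the monomer's own current cube is
#' ignored).
#'
#' @param conf A `dl_conformation`.
#' @param index Monomer index (1-based).
#' @param proposed Integer position of length 3.
#' @return `TRUE` when the proposed cube shares no lattice site with any
#'   other monomer's cube.
#' @export
dl_check_excluded_volume <- function(conf, index, proposed) {
  stopifnot(inherits(conf, "dl_conformation"))
  cpp_check_excluded_volume(conf$positions, conf$box, as.integer(index),
                            as.integer(proposed))
}

#' Initialize a chain as a straight rod
#'
#' The starting configuration before equilibration: monomer k sits at
#' (2(k-1), 0, 0), all bonds are (2,0,0) and there are no cross-links.
#'
#' @param n_monomers Chain length N.
#' @param box Optional periodic box edge; defaults to four times the rod
#'   contour length.
#' @return A valid `dl_conformation` with `sweep = 0`.
#' @export
#' @examples
#' conf <- dl_init_chain(5)
#' conf$positions
dl_init_chain <- function(n_monomers, box = NULL) {
  n <- as.integer(n_monomers)
  if (is.na(n) || n < 1L) stop("n_monomers must be a positive integer")
  if (is.null(box)) box <- dl_default_box(n)
  box <- as.integer(box)
  if (n > box %/% 2L)
    stop("chain too long for box: need n_monomers <= box/2")
  pos <- cbind(2L * (seq_len(n) - 1L), 0L, 0L)
  dl_conformation(pos, sweep = 0, box = box)
}
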