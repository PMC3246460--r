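#' Deterministic test-geometry fixtures
#'
#' Generates conformations with known analytic geometry for exercising the
#' analysis machinery:
#' \describe{
#'   \item{rod}{straight lattice chain, bond (2,0,0): collinear, thickness
#'     0, directional correlation 1 everywhere.}
#'   \item{zigzag}{alternating perpendicular lattice bonds (2,0,0) and
#'     (0,2,0): `K(1) = 0`, `K(2) = 1` at level `m = 1`.}
#'   \item{saw}{a seeded self-avoiding BFM chain: the engine run from a
#'     rod with looping off; deterministic given the seed.}
#'   \item{helix}{ideal off-lattice helix with prescribed radius and
#'     pitch about the x axis; carries its analytic geometry as
#'     attributes and is accepted by the analysis operations only, never
#'     by the engine.}
#'   \item{ring}{off-lattice closed circle of radius `radius`, traversed
#'     as an open path; analysis only.}
#' }
#'
#' @param kind One of `"rod"`, `"zigzag"`, `"saw"`, `"helix"`, `"ring"`.
#' @param n Number of monomers / points.
#' @param seed Seed for `"saw"`.
#' @param radius,pitch Helix/ring geometry (lattice units; `pitch` is the
#'   x-advance per point for the helix).
#' @param turn Points per helix turn.
#' @param sweeps Equilibration sweeps for `"saw"`.
#' @return For lattice kinds a `dl_conformation`; for off-lattice kinds a
#'   numeric matrix with attribute `off_lattice = TRUE` plus the analytic
#'   geometry parameters.
#' @export
#' @examples
#' h <- dl_fixture("helix", n = 200, radius = 4)
#' attr(h, "radius")
dl_fixture <- function(kind = c("rod", "zigzag", "saw", "helix", "ring"),
                       n = 100L, seed = 1L, radius = 4, pitch = 0.5,
                       turn = 12L, sweeps = 2000L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 points")
  switch(kind,
    rod = dl_init_chain(n),
    zigzag = {
      k <- seq_len(n) - 1L
      pos <- cbind(2L * ((k + 1L) %/% 2L), 2L * (k %/% 2L), 0L)
      dl_conformation(pos, sweep = 0)
    },
    saw = {
      conf <- dl_init_chain(n)
      dl_advance(conf, dl_params(), sweeps, seed = seed)$conf
    },
    helix = {
      t <- seq_len(n) - 1L
      ang <- 2 * pi * t / turn
      pts <- cbind(pitch * t, radius * cos(ang), radius * sin(ang))
      structure(pts, off_lattice = TRUE, radius = radius, pitch = pitch,
                turn = as.integer(turn))
    },
    ring = {
      ang <- 2 * pi * (seq_len(n) - 1L) / n
      pts <- cbind(radius * cos(ang), radius * sin(ang), 0)
      structure(pts, off_lattice = TRUE, radius = radius)
    })
}
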