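# A hairpin: an outbound row of monomers along +x and a return row offset
# by (0, 2, 1), so each opposite pair sits at a bond-set displacement.
# Gives a conformation with many simultaneous cross-link candidates.
hairpin_conformation <- function(n_arm = 25L) {
  up <- cbind(2L * (seq_len(n_arm) - 1L), 0L, 0L)
  down <- cbind(rev(up[, 1]), 2L, 1L)
  dl_conformation(rbind(up, down))
}

# Off-lattice worm-like chains: unit-step walk whose direction diffuses on
# the sphere, giving K(s) = exp(-s/s0) with s0 = 2 / sigma^2.
wlc_points <- function(n_points, sigma, step = 2) {
  u <- c(1, 0, 0)
  pts <- matrix(0, n_points, 3)
  for (k in 2:n_points) {
    perp <- rnorm(3)
    perp <- perp - sum(perp * u) * u
    perp <- perp / sqrt(sum(perp^2))
    ang <- sigma * abs(rnorm(1))
    u <- cos(ang) * u + sin(ang) * perp
    u <- u / sqrt(sum(u^2))
    pts[k, ] <- pts[k - 1, ] + step * u
  }
  pts
}

expect_valid <- function(conf, cutoff = 0L) {
  expect_true(dl_validate(conf, cutoff = cutoff))
}
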