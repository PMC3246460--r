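# Shared simulation states for the acceptance suite.  The heavy objects
# (equilibrated coils, condensed chromatids) are computed once per test
# session and reused across test blocks; every accessor is deterministic
# (fixed seeds) so the suite is reproducible end to end.

.acc <- new.env(parent = emptyenv())

acc_get <- function(name, builder) {
  if (!exists(name, envir = .acc)) assign(name, builder(), envir = .acc)
  get(name, envir = .acc)
}

# Loops-off (self-avoiding walk) runs per chain length: long rod -> coil
# equilibration followed by a sampling window, returning the per-sweep
# squared end-to-end series, sampled frames and the final conformation.
SAW_SCHEDULE <- list(
  `50`  = list(equil = 2e5,   sample = 1.2e6),
  `100` = list(equil = 5e5,   sample = 2.4e6),
  `200` = list(equil = 1.2e6, sample = 3e6),
  `256` = list(equil = 1.6e6, sample = 4e5),
  `400` = list(equil = 3e6,   sample = 2.4e6))

acc_saw <- function(n) {
  acc_get(paste0("saw", n), function() {
    sch <- SAW_SCHEDULE[[as.character(n)]]
    seeds <- dl_derive_seeds(4000 + n, 2L)
    conf <- dl_init_chain(n)
    eq <- dl_advance(conf, dl_params(), sch$equil, seed = seeds[1])
    sa <- dl_advance(eq$conf, dl_params(), sch$sample,
                     stride = max(1e4, sch$sample / 25),
                     record_frames = TRUE, seed = seeds[2])
    list(conf = sa$conf, frames = sa$frames, ree2 = sa$ree2)
  })
}

# Force grids for the stretching study (kT per lattice unit): the dense
# chromatid yields around F ~ 0.5-0.8 and decondenses beyond ~1; the
# half-concentration chromatid is considerably softer.
ACC_FORCES <- c(0, 0.3, 0.5, 0.65, 0.8, 1.3)
ACC_FORCES_LO <- c(0, 0.15, 0.3, 0.45)

# Condensed chromatid at chain length n, cutoff c, target concentration.
# Calibration is two-stage: a rough formation probability from pilots
# branched off the coil, half the condensation with it, then a second
# bisection with pilots warm-started from the condensed state (the
# stationary concentration of the condensed phase exceeds the coil-pilot
# value because condensation itself creates contact partners), and the
# remaining condensation with the refined probability.
acc_condensed <- function(n, cutoff, target = 1.0, condense = 2e6,
                          sample = 4e5, lifetime = 100,
                          pilot_sweeps = 3e4, tol = 0.1, max_iter = 8L,
                          stride = 5000) {
  key <- sprintf("cond_%d_%d_%g", n, cutoff, target)
  acc_get(key, function() {
    saw <- acc_saw(n)$conf
    params <- dl_params(cutoff = cutoff, lifetime = lifetime)
    seedbase <- 9000 + n + cutoff * 7 + round(100 * target)
    p1 <- dl_calibrate_p(target, n, params, tol = tol,
                         pilot_sweeps = pilot_sweeps, max_iter = max_iter,
                         seed = seedbase, start = saw)
    params$p_form <- as.numeric(p1)
    seeds <- dl_derive_seeds(seedbase + 1, 3L)
    half <- dl_advance(saw, params, condense / 2, seed = seeds[1])$conf
    p2 <- dl_calibrate_p(target, n, params, tol = tol,
                         pilot_sweeps = pilot_sweeps, max_iter = max_iter,
                         seed = seedbase + 7, start = half)
    params$p_form <- as.numeric(p2)
    cd <- dl_advance(half, params, condense / 2, seed = seeds[2])
    sa <- dl_advance(cd$conf, params, sample, stride = stride,
                     record_frames = TRUE, seed = seeds[3])
    list(conf = sa$conf, frames = sa$frames, params = params,
         p_form = as.numeric(p2), achieved_pilot = attr(p2, "achieved"),
         concentration = mean(sa$n_links) / n, ree2 = sa$ree2)
  })
}
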