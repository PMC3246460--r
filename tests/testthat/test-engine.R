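test_that("sweeps are reproducible and advance the counter", {
  conf <- dl_init_chain(25)
  p <- dl_params(cutoff = 10, p_form = 0.2, lifetime = 30)
  a <- dl_advance(conf, p, 500, seed = 4)
  b <- dl_advance(conf, p, 500, seed = 4)
  expect_identical(a$conf$positions, b$conf$positions)
  expect_identical(a$conf$links, b$conf$links)
  expect_identical(a$ree2, b$ree2)
  expect_equal(a$conf$sweep, 500)
  c2 <- dl_advance(a$conf, p, 250, seed = 5)$conf
  expect_equal(c2$sweep, 750)
  expect_valid(c2, cutoff = 10)
})

test_that("conformations remain valid along a looped, pulled run", {
  conf <- dl_init_chain(40)
  p <- dl_params(cutoff = 20, p_form = 0.3, lifetime = 20, force = 0.2)
  out <- dl_advance(conf, p, 3000, stride = 500, record_frames = TRUE,
                    seed = 8)
  expect_length(out$frames, 6L)
  for (fr in out$frames) expect_valid(fr, cutoff = 20)
  # occupancy rebuild (validator) agrees with the incrementally
  # maintained index after thousands of moves: no overlap ever slips in
  expect_valid(out$conf, cutoff = 20)
})

test_that("end-monomer pulling obeys the Metropolis factor exp(F dR)", {
  # two-monomer chain: stationary distribution over bond vectors is
  # P(b) proportional to exp(F |b|); compare frequency ratios of the
  # bond-length classes against the closed form
  f <- 0.8
  conf <- dl_init_chain(2)
  p <- dl_params(cutoff = 2, p_form = 0, force = f)
  out <- dl_advance(conf, p, 60000, record_keys = TRUE, seed = 13)
  keys <- out$state_keys[-(1:5000)]
  decode <- function(k) {
    c(k %/% 49 - 3, (k %/% 7) %% 7 - 3, k %% 7 - 3)
  }
  lens <- vapply(unique(keys), function(k) sqrt(sum(decode(k)^2)), 1)
  counts <- as.numeric(table(keys)[as.character(unique(keys))])
  # multiplicity-corrected Boltzmann weights over the 5 length classes
  b <- dl_bond_vectors()
  blen <- sqrt(rowSums(b^2))
  cls <- sort(unique(round(blen, 6)))
  mult <- table(round(blen, 6))
  obs <- vapply(cls, function(L) sum(counts[abs(lens - L) < 1e-6]), 1)
  expected <- as.numeric(mult) * exp(f * cls)
  expected <- expected / sum(expected) * sum(obs)
  # chi-square-style agreement, generous to autocorrelation
  expect_gt(cor(obs, expected), 0.99)
  expect_lt(max(abs(obs - expected) / expected), 0.25)
})

test_that("mean extension is non-decreasing in the pulling force", {
  ree <- vapply(c(0, 0.3, 1.0), function(f) {
    conf <- dl_init_chain(20)
    out <- dl_advance(conf, dl_params(cutoff = 5, p_form = 0, force = f),
                      20000, seed = 21)
    mean(sqrt(out$ree2[-(1:10000)]))
  }, 1)
  expect_true(all(diff(ree) > 0))
})

test_that("zero-sampling schedules give empty frame lists with provenance", {
  traj <- dl_run(12, dl_params(cutoff = 5, p_form = 0.2, lifetime = 10),
                 dl_schedule(200, 200, 0, stride = 50, seed = 2))
  expect_length(traj$frames, 0L)
  expect_equal(traj$provenance$seed, 2L)
  expect_length(traj$provenance$sub_seeds, 3L)
  expect_equal(traj$provenance$stage_boundaries, c(200, 400, 400))
  expect_equal(traj$final$sweep, 400)
})

test_that("equilibration detection finds the burn-in end", {
  expect_equal(dl_measure_equilibration(rep(3.2, 200)), 0L)
  step <- c(rep(10, 150), rep(0, 450)) + rnorm(600, sd = 0.05)
  est <- dl_measure_equilibration(step)
  expect_gte(est, 140)
  expect_lt(est, 500)
  # AR(1) started far from its mean relaxes within ~5 tau
  set.seed(11)
  phi <- 0.9
  tau_relax <- -1 / log(phi)  # ~9.5 steps
  x <- numeric(3000)
  x[1] <- 50
  for (k in 2:3000) x[k] <- phi * x[k - 1] + rnorm(1)
  est <- dl_measure_equilibration(x)
  expect_lt(est, 5 * tau_relax * 10)
  expect_error(dl_measure_equilibration(rnorm(50)), "short")
})
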