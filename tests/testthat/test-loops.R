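test_that("candidate detection respects cutoff, proximity and separation", {
  rod <- dl_init_chain(80)
  # straight rod: no non-adjacent pair is within bonding range
  expect_equal(nrow(dl_find_candidates(rod, dl_params(cutoff = 50))), 0L)

  hp <- hairpin_conformation(25)
  cand <- dl_find_candidates(hp, dl_params(cutoff = 50))
  expect_gt(nrow(cand), 0L)
  expect_true(all(cand[, "j"] - cand[, "i"] >= 2))
  expect_true(all(cand[, "j"] - cand[, "i"] <= 50))
  # every candidate displacement is an allowed bond vector
  for (k in seq_len(nrow(cand))) {
    d <- hp$positions[cand[k, "j"], ] - hp$positions[cand[k, "i"], ]
    expect_true(dl_is_bond_vector(d))
  }
  # a small cutoff excludes genomically distant pairs
  cand5 <- dl_find_candidates(hp, dl_params(cutoff = 5))
  expect_true(all(cand5[, "j"] - cand5[, "i"] <= 5))
  # ordering is ascending (i, j)
  expect_false(is.unsorted(cand[, "i"]))
})

test_that("link formation follows the formation probability", {
  hp <- hairpin_conformation(25)
  p0 <- dl_attempt_link_formation(hp, dl_params(cutoff = 50, p_form = 0),
                                  seed = 5)
  expect_equal(nrow(p0$links), 0L)

  p1 <- dl_attempt_link_formation(hp, dl_params(cutoff = 50, p_form = 1),
                                  seed = 5)
  cand <- dl_find_candidates(hp, dl_params(cutoff = 50))
  expect_equal(nrow(p1$links), nrow(cand))
  expect_valid(p1, cutoff = 50)
  expect_true(all(p1$links[, "expiry"] > p1$sweep))

  # binomial check: across many seeds each candidate forms with p = 0.5
  n_cand <- nrow(cand)
  formed <- vapply(1:40, function(s) {
    nrow(dl_attempt_link_formation(
      hp, dl_params(cutoff = 50, p_form = 0.5), seed = s)$links)
  }, 1)
  n_trials <- 40 * n_cand
  frac <- sum(formed) / n_trials
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_trials))
})

test_that("lifetime draws have mean lambda and links expire on schedule", {
  hp <- hairpin_conformation(25)
  lambda <- 40
  draws <- unlist(lapply(1:500, function(s) {
    l <- dl_attempt_link_formation(
      hp, dl_params(cutoff = 50, p_form = 1, lifetime = lambda),
      seed = s)$links
    l[, "expiry"] - hp$sweep - 1
  }))
  expect_gt(length(draws), 1e4)
  expect_lt(abs(mean(draws) - lambda), 3 * sd(draws) / sqrt(length(draws)))

  conf <- dl_attempt_link_formation(hp, dl_params(cutoff = 50, p_form = 1),
                                    seed = 2)
  conf$links[, "expiry"] <- 100L
  conf$sweep <- 100
  expect_equal(nrow(dl_expire_links(conf)$links), 0L)
  conf$sweep <- 99
  expect_equal(nrow(dl_expire_links(conf)$links), nrow(conf$links))
  empty <- dl_init_chain(5)
  expect_equal(nrow(dl_expire_links(empty)$links), 0L)
})

test_that("loop concentration and size histogram", {
  conf <- hairpin_conformation(25)
  expect_equal(dl_loop_concentration(conf), 0)
  conf2 <- dl_attempt_link_formation(conf, dl_params(cutoff = 50, p_form = 1),
                                     seed = 1)
  expect_equal(dl_loop_concentration(conf2),
               nrow(conf2$links) / nrow(conf2$positions))

  # unit mass at the single loop size
  rodish <- hairpin_conformation(10)
  one <- rodish
  one$links <- cbind(i = 3L, j = 13L, expiry = 1000L)
  h <- dl_loop_size_histogram(one, cutoff = 19)
  expect_equal(h$count[h$size == 10], 1)
  expect_equal(sum(h$count), 1)
  h0 <- dl_loop_size_histogram(rodish, cutoff = 19)
  expect_true(all(h0$count == 0))

  # sizes planted uniformly on [2, c] give a flat histogram
  set.seed(42)
  cmax <- 20L
  planted <- lapply(1:200, function(k) {
    x <- rodish
    s <- sample(2:cmax, 1)
    x$links <- cbind(i = 1L, j = 1L + s, expiry = 1000L)
    x
  })
  hh <- dl_loop_size_histogram(planted, cutoff = cmax)
  expect_equal(sum(hh$count), 1)
  p_bin <- 1 / (cmax - 1)
  se <- sqrt(p_bin * (1 - p_bin) / 200)
  expect_true(all(abs(hh$count - p_bin) < 4 * se))
})

test_that("p = 0 reduces the engine to a pure self-avoiding walk", {
  conf <- dl_init_chain(30)
  a <- dl_advance(conf, dl_params(cutoff = 10, p_form = 0), 2000, seed = 9)
  b <- dl_advance(conf, dl_params(cutoff = 40, p_form = 0), 2000, seed = 9)
  expect_identical(a$conf$positions, b$conf$positions)
  expect_equal(nrow(a$conf$links), 0L)
  expect_identical(a$ree2, b$ree2)
})

test_that("formation probability calibration hits the target concentration", {
  params <- dl_params(cutoff = 15, lifetime = 50)
  target <- 0.6
  p <- dl_calibrate_p(target, n_monomers = 60, params, tol = 0.1,
                      pilot_sweeps = 40000, saw_sweeps = 20000, seed = 3)
  expect_gt(p, 0)
  expect_lt(abs(attr(p, "achieved") - target) / target, 0.1)
  # re-run with a fresh seed reproduces the target within 2x tolerance
  pp <- params
  pp$p_form <- as.numeric(p)
  saw <- dl_advance(dl_init_chain(60), dl_params(cutoff = 15), 20000,
                    seed = 77)$conf
  o <- dl_advance(saw, pp, 40000, seed = 78)
  conc <- mean(o$n_links[-(1:20000)]) / 60
  expect_lt(abs(conc - target) / target, 0.2)
  expect_identical(as.numeric(dl_calibrate_p(0, 60, params)), 0)
})
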