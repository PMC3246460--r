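test_that("coarse backbone averages disjoint blocks", {
  rod <- dl_init_chain(12)
  bb <- dl_coarse_backbone(rod, 3)
  expect_equal(bb$points[, 1], c(2, 8, 14, 20))
  expect_equal(nrow(bb$points), 4L)
  expect_equal(dl_coarse_backbone(rod, 1)$points,
               rod$positions + 0, ignore_attr = TRUE)
  expect_equal(dl_coarse_backbone(rod, 12)$points,
               matrix(colMeans(rod$positions), 1), ignore_attr = TRUE)
  # trailing remainder is dropped
  expect_equal(nrow(dl_coarse_backbone(dl_init_chain(14), 3)$points), 4L)
  expect_error(dl_coarse_backbone(rod, 13), "exceeds")
})

test_that("smooth backbone slides a window of m monomers", {
  rod <- dl_init_chain(10)
  bb <- dl_smooth_backbone(rod, 4)
  expect_equal(nrow(bb$points), 7L)
  # rod input stays collinear along x
  expect_true(all(bb$points[, 2] == 0) && all(bb$points[, 3] == 0))
  expect_equal(diff(bb$points[, 1]), rep(2, 6))
  expect_equal(dl_smooth_backbone(rod, 1)$points, rod$positions + 0,
               ignore_attr = TRUE)
})

test_that("directional correlation: rod, zigzag and isotropic oracles", {
  rod <- dl_init_chain(20)
  prof <- dl_directional_correlation(dl_coarse_backbone(rod, 1))
  expect_equal(prof$K[1], 1)
  expect_true(all(abs(prof$K - 1) < 1e-12))

  zz <- dl_fixture("zigzag", 21)
  pz <- dl_directional_correlation(dl_coarse_backbone(zz, 1))
  expect_equal(pz$K[pz$s == 1], 0, tolerance = 1e-12)
  expect_equal(pz$K[pz$s == 2], 1, tolerance = 1e-12)

  # ensemble of isotropic random-direction chains: K(s >= 1) ~ 0
  set.seed(31)
  ens <- lapply(1:60, function(k) {
    steps <- matrix(rnorm(30 * 3), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2))
    apply(rbind(0, 2 * steps), 2, cumsum)
  })
  pi_ <- dl_directional_correlation(lapply(ens, dl_smooth_backbone, m = 1))
  expect_equal(pi_$K[1], 1)
  expect_true(all(abs(pi_$K) <= 1 + 1e-12))
  inner <- pi_$s >= 1 & pi_$s <= 15
  expect_true(all(abs(pi_$K[inner]) < 4 * pi_$stderr[inner] + 0.02))
})

test_that("persistence length integrates the correlation profile", {
  s0 <- 15
  s <- 0:120
  prof <- data.frame(s = s, K = exp(-s / s0))
  est <- dl_persistence_length(prof, mean_bond_length = 2)
  expect_equal(est$lp, s0 * 2, tolerance = 0.02 * s0 * 2)
  expect_false(est$rod_like)
  expect_equal(est$lp_exp, s0 * 2, tolerance = 1e-6)

  # brute-force trapezoid oracle on a geometric profile
  K <- c(1, 0.5, 0.25, 0.125, 0.0625)
  prof2 <- data.frame(s = 0:4, K = K)
  brute <- sum((K[-5] + K[-1]) / 2)
  expect_equal(dl_persistence_length(prof2, 1)$lp, brute)

  # truncation at the first non-positive value
  prof3 <- data.frame(s = 0:3, K = c(1, -0.1, 0.5, 0.5))
  est3 <- dl_persistence_length(prof3, 1)
  expect_equal(est3$lp, (1 - 0.1) / 2)
  expect_equal(est3$truncated_at, 1L)

  # rod-like profile is flagged, not reported as a number
  rodp <- data.frame(s = 0:10, K = rep(1, 11))
  expect_true(dl_persistence_length(rodp, 1)$rod_like)
})

test_that("coarse-level selection favours exponential decay", {
  set.seed(33)
  ens <- lapply(1:40, function(k) wlc_points(120, sigma = 0.45))
  sel <- dl_select_coarse_level(ens, c(1, 2, 4))
  fits <- attr(sel, "fits")
  expect_gte(fits$r2[fits$m == sel], 0.95)
  # single candidate level is returned as-is
  one <- dl_select_coarse_level(ens, 2)
  expect_equal(as.integer(one), 2L)
  # rods have no decay to fit
  rods <- lapply(1:5, function(k) dl_init_chain(60))
  expect_error(dl_select_coarse_level(rods, c(1, 2, 4)), "degenerate")
})

test_that("chromatid length is the backbone contour length", {
  expect_equal(dl_chromatid_length(matrix(c(0, 2, 4, 0, 0, 0, 0, 0, 0), 3)),
               4)
  expect_equal(dl_chromatid_length(matrix(c(1, 1, 1), 1)), 0)
  square <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(dl_chromatid_length(square), 6)
})

test_that("compaction ratio matches an independent direct computation", {
  rod <- dl_init_chain(40)
  expect_equal(dl_compaction_ratio(list(rod), m = 1), 1, tolerance = 1e-12)
  # hairpin folded in half: compare against a from-scratch computation of
  # (N-1) x mean bond length / sliding-window contour, done by hand
  n <- 40
  arm <- n / 2
  fold <- rbind(cbind(2 * (1:arm), 0, 0), cbind(2 * (arm:1), 2, 1))
  for (m in c(2L, 10L, 20L)) {
    sw <- t(vapply(1:(n - m + 1L), function(k)
      colMeans(fold[k:(k + m - 1L), , drop = FALSE]), numeric(3)))
    contour <- sum(sqrt(rowSums(diff(sw)^2)))
    bbar <- mean(sqrt(rowSums(diff(fold)^2)))
    expect_equal(dl_compaction_ratio(list(fold), m = m),
                 (n - 1) * bbar / contour, tolerance = 1e-12)
  }
  # folding in half compacts: ratio above 1 and growing with the window
  r <- vapply(c(2L, 10L, 20L), function(m)
    dl_compaction_ratio(list(fold), m = m), 1)
  expect_true(all(r > 1))
  expect_true(all(diff(r) > 0))
})

test_that("radial density peaks at the helix radius and conserves mass", {
  hx <- dl_fixture("helix", n = 600, radius = 4, pitch = 0.4, turn = 20)
  # the helix axis is the x axis; a straight reference backbone
  axis_pts <- cbind(seq(0, max(hx[, 1]), length.out = 200), 0, 0)
  dens <- dl_radial_density(hx, axis_pts, bin_width = 1)
  expect_equal(dens$r_mid[which.max(dens$density)], 4.5, tolerance = 1)
  # conservation: sum(density x shell volume) = N at any bin width
  for (bw in c(0.5, 1, 2)) {
    d <- dl_radial_density(hx, axis_pts, bin_width = bw)
    L <- attr(d, "backbone_length")
    expect_equal(sum(d$density * 2 * pi * d$r_mid * bw * L), 600)
  }
  # all monomers on the backbone: innermost bin carries everything
  rod <- dl_init_chain(30)
  bb <- dl_smooth_backbone(rod, 1)
  d0 <- dl_radial_density(rod, bb, bin_width = 1)
  expect_equal(d0$count[1], 30)
})

test_that("thickness is the theta-quantile of perpendicular distances", {
  hx <- dl_fixture("helix", n = 400, radius = 3, pitch = 0.4, turn = 20)
  axis_pts <- cbind(seq(0, max(hx[, 1]), length.out = 100), 0, 0)
  expect_equal(dl_thickness(hx, axis_pts, 0.5), 3, tolerance = 0.05)
  expect_equal(dl_thickness(hx, axis_pts, 1.0), 3, tolerance = 0.05)
  # exact quantile convention on a constructed distance set
  pts <- cbind(0, 1:100, 0)
  axis2 <- cbind(c(-1000, 1000), 0, 0)
  expect_equal(dl_thickness(pts, axis2, 0.9), 90)
  th <- vapply(c(0.3, 0.6, 0.9, 1), function(q)
    dl_thickness(pts, axis2, q), 1)
  expect_true(all(diff(th) >= 0))
})
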