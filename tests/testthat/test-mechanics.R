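fake_curve <- function(force, extension, thickness = NULL,
                       se_extension = NULL) {
  df <- data.frame(force = force, extension = extension)
  if (!is.null(thickness)) df$thickness <- thickness
  if (!is.null(se_extension)) df$se_extension <- se_extension
  df
}

test_that("linear-regime fit recovers exact lines and flags single points", {
  eps <- seq(0, 2, by = 0.25)
  fit <- dl_fit_linear_regime(fake_curve(2 * eps, eps))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)

  one <- dl_fit_linear_regime(fake_curve(c(0, 0.6), c(0, 0.3)))
  expect_equal(one$slope, 2)
  expect_true(is.na(one$r_squared))
  expect_error(dl_fit_linear_regime(fake_curve(0, 0)), "insufficient")
})

test_that("the detected linear-regime end matches the constructed curve", {
  eps <- c(seq(0.2, 2, by = 0.2), seq(2.5, 5, by = 0.5))
  f <- ifelse(eps <= 2, 0.1 * eps, 0.2)   # linear to 2, then flat
  end <- dl_linear_regime_end(fake_curve(f, eps), r2_min = 0.98)
  # detected end sits at the constructed break, within one grid step
  expect_gte(end, 2)
  expect_lte(end, 2.5)
  strict <- dl_linear_regime_end(fake_curve(f, eps), r2_min = 0.9999)
  expect_equal(strict, 2)
})

test_that("Young's modulus of a cylinder scales as slope over area", {
  expect_equal(dl_youngs_modulus(pi, 1), 1)
  expect_equal(dl_youngs_modulus(8 * pi, 2), 2)
  expect_equal(dl_youngs_modulus(3, 2), dl_youngs_modulus(3, 1) / 4)
  expect_error(dl_youngs_modulus(1, 0), "positive")
})

test_that("bending moduli: thermal and cylinder routes", {
  expect_equal(dl_bending_measured(5), 5)
  expect_equal(dl_bending_measured(0), 0)
  expect_equal(dl_bending_measured(c(1, 2, 4)), c(1, 2, 4))
  expect_equal(dl_bending_calculated(1, 2), 4 * pi)
  expect_equal(dl_bending_calculated(1, 0), 0)
  # quartic in the radius
  expect_equal(dl_bending_calculated(2, 4) / dl_bending_calculated(2, 2), 16)
})

test_that("Poisson's ratio from width-extension curves", {
  eps <- seq(0, 2, by = 0.25)
  # constant width: nu = 0
  c0 <- fake_curve(0.1 * eps, eps, thickness = rep(8, length(eps)))
  expect_equal(dl_poissons_ratio(c0)$nu, 0, tolerance = 1e-12)
  # exactly linear: width strain -0.01 at extension +0.1 -> nu = 0.1
  c1 <- fake_curve(0.1 * eps, eps, thickness = 8 * (1 - 0.1 * eps))
  expect_equal(dl_poissons_ratio(c1)$nu, 0.1, tolerance = 1e-9)
  # curved onset converging to slope -0.05
  eps2 <- seq(0, 2, by = 0.125)
  wrel <- -0.05 * eps2 + 0.02 * exp(-eps2 / 0.15)
  c2 <- fake_curve(0.1 * eps2, eps2, thickness = 10 * (1 + wrel - wrel[1]))
  est <- dl_poissons_ratio(c2, r2_min = 0.999)
  expect_equal(est$nu, 0.05, tolerance = 0.1)
  # a non-monotone width series is flagged
  c3 <- fake_curve(0.1 * eps, eps,
                   thickness = 8 + 0.5 * sin(8 * eps))
  expect_warning(dl_poissons_ratio(c3), "non-monotone")
})

test_that("loop response summarises per-force loop statistics", {
  conf <- hairpin_conformation(20)
  mk <- function(sizes) {
    x <- conf
    x$links <- cbind(i = 1L, j = 1L + as.integer(sizes),
                     expiry = 1000L)
    list(x)
  }
  frames <- list(`0` = mk(c(3, 3, 3)), `0.1` = mk(c(3, 20)))
  resp <- dl_loop_response(frames, threshold = 10)
  expect_equal(resp$force, c(0, 0.1))
  expect_equal(resp$frac_small, c(1, 0.5))
  expect_equal(resp$frac_large, c(0, 0.5))
  expect_equal(resp$mean_size, c(3, 11.5))
  expect_equal(resp$concentration[1], 3 / 40)
  expect_error(dl_loop_response(frames[1], 10), "2 forces")
})

test_that("force-extension machinery produces a coherent small-chain curve", {
  sched <- dl_schedule(stage1 = 4000, stage2 = 8000, sampling = 20000,
                       stride = 2000, seed = 19)
  params <- dl_params(cutoff = 12, p_form = 0.15, lifetime = 30)
  curve <- dl_force_extension(40, params, forces = c(0, 0.4, 1.2), sched,
                              m = 5)
  expect_s3_class(curve, "dl_force_extension")
  expect_equal(curve$extension[curve$force == 0], 0)
  expect_equal(curve$se_extension[curve$force == 0], 0)
  # extension non-decreasing along the grid within error bars
  ord <- order(curve$force)
  gain <- diff(curve$extension[ord])
  tol <- 2 * sqrt(diff(curve$se_extension[ord])^2 +
                    curve$se_extension[ord][-1]^2)
  expect_true(all(gain > -tol - 0.05))
  expect_true(all(curve$loop_concentration >= 0))
  frames <- attr(curve, "frames")
  expect_length(frames, 3L)
  for (fr in frames[[2]]) expect_valid(fr, cutoff = 12)
})
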