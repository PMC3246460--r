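ree_of <- function(conf) {
  p <- conf$positions
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

se_of_mean <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  tau <- if (length(x) >= 100L)
    tryCatch(suppressWarnings(dl_integrated_autocorr_time(x)$tau_int),
             error = function(e) 0.5)
  else 0.5
  sd(x) / sqrt(max(1, length(x) / (2 * tau)))
}

#' Equilibrium force-extension curve
#'
#' For every force on the grid an independent run is performed: the chain
#' is equilibrated to a self-avoiding walk, condensed with the looping
#' mechanism at zero force, re-equilibrated with the constant stretching
#' force switched on and then sampled.  When a pre-condensed conformation
#' is supplied via `from`, the per-force runs branch from that single
#' condensed state with independent seeds and a fresh force
#' re-equilibration stage each (a reduced-cost protocol whose force points
#' share only the initial condition, not any annealing history).  The mean
#' relative extension is
#' `eps(F) = (<R_F> - <R_0>) / <R_0>` with `<R_0>` taken from the
#' zero-force member of the same grid.  Mean thickness (at fixed
#' coarse-graining level `m`, the level chosen for the unstretched chain)
#' and mean loop statistics are recorded per force.
#'
#' @param n_monomers Chain length N.
#' @param params A `dl_params`; its `force` field is ignored.
#' @param forces Numeric force grid in kT per lattice unit; must include 0.
#' @param schedule A `dl_schedule`; `stage2` is also used for the
#'   force re-equilibration stage.
#' @param m Coarse-graining level for thickness estimation.
#' @param theta Thickness quantile.
#' @param from Optional condensed `dl_conformation` to branch the
#'   per-force runs from (skips the loops-off and condensation stages).
#' @return An object of class `dl_force_extension`: data frame with
#'   columns `force`, `mean_ree`, `se_ree`, `extension`, `se_extension`,
#'   `thickness`, `loop_concentration`, `mean_loop_size`; attributes `r0`,
#'   `n`, `m` and `frames` (per-force frame lists, for loop-response
#'   analysis).
#' @export
dl_force_extension <- function(n_monomers, params, forces, schedule,
                               m = 25L, theta = 0.9, from = NULL) {
  stopifnot(inherits(params, "dl_params"), inherits(schedule, "dl_schedule"))
  forces <- sort(unique(as.numeric(forces)))
  if (!any(forces == 0)) stop("the force grid must include 0")
  seeds <- dl_derive_seeds(schedule$seed, 4L * length(forces))

  rows <- vector("list", length(forces))
  frames_by_force <- vector("list", length(forces))
  for (fi in seq_along(forces)) {
    F <- forces[fi]
    s <- seeds[(4L * (fi - 1L) + 1L):(4L * fi)]
    if (is.null(from)) {
      conf <- dl_init_chain(n_monomers)
      saw_params <- params; saw_params$p_form <- 0; saw_params$force <- 0
      conf <- dl_advance(conf, saw_params, schedule$stage1, seed = s[1])$conf
      cond_params <- params; cond_params$force <- 0
      conf <- dl_advance(conf, cond_params, schedule$stage2, seed = s[2])$conf
    } else {
      stopifnot(inherits(from, "dl_conformation"))
      conf <- from
    }
    pull_params <- params; pull_params$force <- F
    conf <- dl_advance(conf, pull_params, schedule$stage2, seed = s[3])$conf
    out <- dl_advance(conf, pull_params, schedule$sampling,
                      stride = schedule$stride, record_frames = TRUE,
                      seed = s[4])
    ree <- sqrt(out$ree2)
    th <- vapply(out$frames, function(fr)
      dl_thickness(fr, dl_smooth_backbone(fr, m), theta), 1)
    sizes <- unlist(lapply(out$frames, function(fr)
      if (nrow(fr$links)) fr$links[, "j"] - fr$links[, "i"] else numeric(0)))
    rows[[fi]] <- data.frame(
      force = F,
      mean_ree = mean(ree),
      se_ree = se_of_mean(ree),
      thickness = mean(th),
      se_thickness = sd(th) / sqrt(length(th)),
      loop_concentration = mean(out$n_links) / n_monomers,
      mean_loop_size = if (length(sizes)) mean(sizes) else NA_real_)
    frames_by_force[[fi]] <- out$frames
  }
  tab <- do.call(rbind, rows)
  r0 <- tab$mean_ree[tab$force == 0]
  se_r0 <- tab$se_ree[tab$force == 0]
  tab$extension <- (tab$mean_ree - r0) / r0
  tab$se_extension <- sqrt((tab$se_ree / r0)^2 +
                             (tab$mean_ree * se_r0 / r0^2)^2)
  tab$se_extension[tab$force == 0] <- 0
  attr(tab, "r0") <- r0
  attr(tab, "n") <- as.integer(n_monomers)
  attr(tab, "m") <- as.integer(m)
  attr(tab, "frames") <- setNames(frames_by_force, forces)
  class(tab) <- c("dl_force_extension", "data.frame")
  tab
}

#' Fit the linear regime of a force-extension curve
#'
#' Weighted least squares of force on relative extension through the
#' origin (`eps(0) = 0` holds by construction) over `0 < eps <= eps_max`.
#' Weights are inverse squared standard errors of the extension when
#' available.
#'
#' @param curve A `dl_force_extension` (or data frame with columns
#'   `force`, `extension` and optionally `se_extension`).
#' @param eps_max Upper end of the fitted extension range (default 2, i.e.
#'   up to twice the native length).
#' @return A list with `slope` (the force modulus, kT per lattice unit per
#'   unit strain), `r_squared` (`NA` with a flag when only one point is
#'   available), `n_points` and `residuals`.
#' @export
dl_fit_linear_regime <- function(curve, eps_max = 2) {
  use <- curve$extension > 0 & curve$extension <= eps_max &
    is.finite(curve$force)
  eps <- curve$extension[use]
  f <- curve$force[use]
  if (length(eps) < 1L) stop("insufficient points in the linear window")
  w <- rep(1, length(eps))
  if (!is.null(curve$se_extension)) {
    se <- curve$se_extension[use]
    if (all(is.finite(se)) && all(se > 0)) w <- 1 / se^2
  }
  slope <- sum(w * eps * f) / sum(w * eps^2)
  res <- f - slope * eps
  r2 <- if (length(eps) >= 2L) 1 - sum(w * res^2) / sum(w * f^2) else NA_real_
  list(slope = slope, r_squared = r2, n_points = length(eps),
       residuals = res)
}

#' Detect the end of the linear regime
#'
#' Scans the curve's extension values as candidate upper limits and
#' returns the largest `eps_max` for which the through-origin fit keeps
#' `R^2 >= r2_min`.
#'
#' @inheritParams dl_fit_linear_regime
#' @param r2_min Goodness-of-fit threshold (default 0.98).
#' @return The detected linear-regime end (an extension value).
#' @export
dl_linear_regime_end <- function(curve, r2_min = 0.98) {
  eps <- sort(curve$extension[curve$extension > 0])
  if (length(eps) < 3L) stop("need at least 3 positive-extension points")
  best <- NA_real_
  for (e in eps[-(1:2)]) {
    fit <- dl_fit_linear_regime(curve, eps_max = e)
    if (is.finite(fit$r_squared) && fit$r_squared >= r2_min) best <- e
  }
  if (is.na(best)) stop("no linear regime at the requested r2_min")
  best
}

#' Young's modulus of a cylindrical chromatid
#'
#' Stress per unit strain for a homogeneous cylinder:
#' `Y = slope / (pi * radius^2)`.
#'
#' @param force_modulus Slope of force vs relative extension (kT per
#'   lattice unit).
#' @param radius Chromatid radius in lattice units.
#' @return Young's modulus in kT per lattice unit cubed.
#' @export
dl_youngs_modulus <- function(force_modulus, radius) {
  if (radius <= 0) stop("radius must be positive")
  force_modulus / (pi * radius^2)
}

#' Bending modulus from the persistence length
#'
#' In thermal units the persistence length is the bending modulus:
#' `B = l_p * kT` with `kT = 1`.
#'
#' @param persistence_length Persistence length in lattice units (>= 0).
#' @return Bending modulus in kT times lattice units.
#' @export
dl_bending_measured <- function(persistence_length) {
  if (any(persistence_length < 0)) stop("persistence length must be >= 0")
  persistence_length * 1
}

#' Bending modulus of a homogeneous cylinder
#'
#' `B = Y * pi * radius^4 / 4`: the bending stiffness the chromatid would
#' have if it were a homogeneous elastic cylinder with the measured
#' Young's modulus and radius.
#'
#' @param youngs_modulus Young's modulus.
#' @param radius Cylinder radius in lattice units.
#' @return Bending modulus.
#' @export
dl_bending_calculated <- function(youngs_modulus, radius) {
  if (any(youngs_modulus < 0) || any(radius < 0))
    stop("modulus and radius must be >= 0")
  youngs_modulus * pi * radius^4 / 4
}

#' Poisson's ratio from thickness and extension
#'
#' The negative ratio of transverse (relative width) strain to axial
#' strain.  The width-strain vs extension relationship is not linear from
#' the start but converges to a line, so the slope is fitted on the
#' asymptotically linear tail: starting points are dropped from the left
#' until the linear fit of the remaining points reaches `r2_min` (or no
#' more points can be dropped), and the slope of that tail fit gives
#' `nu = -d(width strain)/d(extension)`.
#'
#' @param curve A `dl_force_extension`, or a data frame with columns
#'   `extension` and `thickness` (thickness at zero force defines the
#'   reference width).
#' @param eps_max Restrict to the linear force regime (default 2).
#' @param r2_min Tail-fit goodness threshold.
#' @return A list with `nu`, `slope_r_squared`, `n_points` and
#'   `monotone` (`FALSE` flags a non-monotone width series).
#' @export
dl_poissons_ratio <- function(curve, eps_max = 2, r2_min = 0.98) {
  use <- is.finite(curve$extension) & is.finite(curve$thickness) &
    curve$extension <= eps_max
  eps <- curve$extension[use]
  th <- curve$thickness[use]
  o <- order(eps)
  eps <- eps[o]; th <- th[o]
  if (length(eps) < 3L) stop("need thickness at >= 3 forces")
  w0 <- th[eps == min(eps)][1]
  wrel <- (th - w0) / w0
  monotone <- all(diff(th) <= 0) || all(diff(th) >= 0)
  if (!monotone) warning("non-monotone width series")
  nu <- NA_real_; r2 <- NA_real_; np <- NA_integer_
  for (k in seq_len(length(eps) - 2L)) {
    idx <- k:length(eps)
    fit <- lm(wrel[idx] ~ eps[idx])
    r2k <- suppressWarnings(summary(fit)$r.squared)
    if (k == 1L || !is.finite(r2) || r2k > r2) {
      nu <- -unname(coef(fit)[2]); r2 <- r2k; np <- length(idx)
    }
    if (is.finite(r2k) && r2k >= r2_min) {
      nu <- -unname(coef(fit)[2]); r2 <- r2k; np <- length(idx)
      break
    }
  }
  list(nu = nu, slope_r_squared = r2, n_points = np, monotone = monotone)
}

#' Loop statistics as a function of applied force
#'
#' Per force: total loop concentration, mean genomic loop size and the
#' fractions of small (`size <= threshold`) and large loops.  In the
#' linear stretching regime the total concentration stays nearly constant
#' while the size distribution shifts from large to small loops; at
#' plateau forces the concentration collapses.
#'
#' @param frames_by_force Named list (names = forces) of frame lists, e.g.
#'   the `frames` attribute of [dl_force_extension()].
#' @param threshold Small/large size threshold (default `cutoff / 2` is a
#'   sensible choice).
#' @return A data frame with columns `force`, `concentration`,
#'   `mean_size`, `frac_small`, `frac_large`.
#' @export
dl_loop_response <- function(frames_by_force, threshold) {
  if (length(frames_by_force) < 2L) stop("need frames for at least 2 forces")
  rows <- lapply(seq_along(frames_by_force), function(k) {
    frames <- frames_by_force[[k]]
    sizes <- unlist(lapply(frames, function(fr)
      if (nrow(fr$links)) fr$links[, "j"] - fr$links[, "i"] else numeric(0)))
    nmono <- nrow(frames[[1]]$positions)
    nl <- mean(vapply(frames, function(fr) nrow(fr$links), 1L))
    data.frame(
      force = as.numeric(names(frames_by_force)[k]),
      concentration = nl / nmono,
      mean_size = if (length(sizes)) mean(sizes) else NA_real_,
      frac_small = if (length(sizes)) mean(sizes <= threshold) else NA_real_,
      frac_large = if (length(sizes)) mean(sizes > threshold) else NA_real_)
  })
  do.call(rbind, rows)
}
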