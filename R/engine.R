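#' Derive independent sub-seeds from a run seed
#'
#' All randomness in a run flows from a single integer seed.  Sub-streams
#' (equilibration stages, pilot runs, per-force runs) use sub-seeds derived
#' by one fixed splitmix-style integer recurrence, so no hidden global RNG
#' state is involved and every seed stays below 2^31.
#'
#' @param seed Integer run seed.
#' @param k Number of sub-seeds.
#' @return An integer vector of length `k`.
#' @export
dl_derive_seeds <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483647
  out <- integer(k)
  for (i in seq_len(k)) {
    s <- (s * 48271 + 104729) %% 2147483647
    out[i] <- as.integer(max(1, s))
  }
  out
}

#' Run schedule
#'
#' The standard two-stage protocol: `stage1` sweeps with the looping
#' mechanism off (equilibration of the start configuration to a
#' self-avoiding walk), `stage2` sweeps with loops on (and pulling, if a
#' force is set), then `sampling` sweeps during which one frame is stored
#' every `stride` sweeps.
#'
#' @param stage1,stage2,sampling Sweep counts (>= 0).
#' @param stride Sweeps between stored frames (>= 1).
#' @param seed Integer run seed.
#' @return A list of class `dl_schedule`.
#' @export
dl_schedule <- function(stage1 = 10000, stage2 = 10000, sampling = 10000,
                        stride = 500, seed = 1L) {
  if (any(c(stage1, stage2, sampling) < 0)) stop("sweep counts must be >= 0")
  if (stride < 1) stop("stride must be >= 1")
  structure(list(stage1 = stage1, stage2 = stage2, sampling = sampling,
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "dl_schedule")
}

#' Advance a conformation by a number of sweeps
#'
#' One sweep = N attempted local moves (uniform random monomer, uniform
#' random unit lattice direction; a move is rejected if any incident bond
#' -- backbone or cross-link -- would leave the bond set or excluded volume
#' would be violated), followed by link expiry and stochastic link
#' formation.  With a positive `force` in `params`, moves of the two end
#' monomers additionally pass a Metropolis test with acceptance
#' `min(1, exp(force * d|Ree|))` for the pulling energy `-force * |Ree|`.
#'
#' The same `(conf, params, nsweeps, seed)` always yields the identical
#' result (bitwise reproducibility).
#'
#' @param conf A `dl_conformation`.
#' @param params A `dl_params`.
#' @param nsweeps Number of sweeps to run.
#' @param stride Frame-recording stride (used when `record_frames = TRUE`).
#' @param record_frames Store a frame every `stride` sweeps?
#' @param record_keys Record a compact per-sweep bond-state key (small
#'   chains only; used for exhaustive-enumeration checks).
#' @param seed Integer seed for the engine RNG.
#' @return A list with elements `conf` (final `dl_conformation`), `frames`
#'   (list of `dl_conformation`, possibly empty), `ree2` (squared
#'   end-to-end distance after every sweep), `n_links` (active link count
#'   after every sweep) and `state_keys`.
#' @export
dl_advance <- function(conf, params, nsweeps, stride = 0L,
                       record_frames = FALSE, record_keys = FALSE, seed = 1L) {
  stopifnot(inherits(conf, "dl_conformation"), inherits(params, "dl_params"))
  out <- cpp_advance(conf$positions, conf$links, conf$sweep,
                     cpp_params(params, conf), as.numeric(nsweeps),
                     as.integer(stride), record_frames, record_keys,
                     as.integer(seed))
  as_conf <- function(fr) {
    dl_conformation(fr$positions, fr$links, fr$sweep, conf$box,
                    validate = FALSE)
  }
  list(conf = as_conf(out),
       frames = lapply(out$frames, as_conf),
       ree2 = out$ree2,
       n_links = out$n_links,
       state_keys = out$state_keys)
}

#' Advance by single sweeps
#'
#' Convenience wrapper over [dl_advance()] for unit-scale experiments.
#'
#' @inheritParams dl_advance
#' @return The advanced `dl_conformation`.
#' @export
dl_sweep <- function(conf, params, nsweeps = 1L, seed = 1L) {
  dl_advance(conf, params, nsweeps, seed = seed)$conf
}

#' Run the full two-stage simulation protocol
#'
#' Stage 1 equilibrates the straight-rod start configuration into a
#' self-avoiding walk (looping and pulling off).  Stage 2 switches the
#' looping mechanism on (and the pulling force, if any) and equilibrates
#' again.  The sampling stage then stores one frame every `stride` sweeps.
#'
#' @param n_monomers Chain length N.
#' @param params A `dl_params`.
#' @param schedule A `dl_schedule`.
#' @param box Optional periodic box edge.
#' @return A `dl_trajectory`: list with `frames`, `n`, `box`, `params`,
#'   `schedule`, `series` (per-stage `ree2` and `n_links` traces),
#'   `final` conformation and a `provenance` block sufficient to reproduce
#'   the run.
#' @export
#' @examples
#' traj <- dl_run(30, dl_params(cutoff = 10, p_form = 0.2, lifetime = 50),
#'                dl_schedule(500, 500, 500, stride = 100, seed = 7))
#' length(traj$frames)
#' dl_loop_concentration(traj$frames[[5]])
dl_run <- function(n_monomers, params, schedule, box = NULL) {
  stopifnot(inherits(params, "dl_params"), inherits(schedule, "dl_schedule"))
  seeds <- dl_derive_seeds(schedule$seed, 3L)
  conf <- dl_init_chain(n_monomers, box = box)

  saw_params <- params
  saw_params$p_form <- 0
  saw_params$force <- 0
  s1 <- dl_advance(conf, saw_params, schedule$stage1, seed = seeds[1])
  s2 <- dl_advance(s1$conf, params, schedule$stage2, seed = seeds[2])
  s3 <- dl_advance(s2$conf, params, schedule$sampling,
                   stride = schedule$stride, record_frames = TRUE,
                   seed = seeds[3])

  structure(list(
    frames = s3$frames,
    n = as.integer(n_monomers),
    box = conf$box,
    params = params,
    schedule = schedule,
    series = list(
      stage1 = list(ree2 = s1$ree2, n_links = s1$n_links),
      stage2 = list(ree2 = s2$ree2, n_links = s2$n_links),
      sampling = list(ree2 = s3$ree2, n_links = s3$n_links)),
    final = s3$conf,
    provenance = list(
      package = "dynloop",
      version = as.character(utils::packageVersion("dynloop")),
      seed = schedule$seed,
      sub_seeds = seeds,
      stage_boundaries = cumsum(c(schedule$stage1, schedule$stage2,
                                  schedule$sampling)))),
    class = "dl_trajectory")
}

#' @export
print.dl_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dl_trajectory> N = %d, %d frame(s), cutoff %d, p_form %.4g, force %g, seed %d\n",
    x$n, length(x$frames), x$params$cutoff, x$params$p_form,
    x$params$force, x$schedule$seed))
  invisible(x)
}

#' Detect equilibration of an observable series
#'
#' Returns the first sweep index after which the running mean of the
#' remaining series stays within two standard errors of the mean of the
#' second half.  Concretely, with `r(t) = mean(series[t..n])`, the result
#' is the smallest `t` (0-based) such that `|r(j) - mu2| <= 2 se(j)` for
#' all `j >= t`, where `mu2` is the second-half mean and `se(j)` is the
#' autocorrelation-corrected standard error of a mean over `n - j` points
#' (integrated autocorrelation time estimated on the second half).
#'
#' @param series Numeric observable trace (length >= 100).
#' @return The 0-based sweep index of equilibration (0 when the series is
#'   stationary from the start).
#' @export
dl_measure_equilibration <- function(series) {
  n <- length(series)
  if (n < 100L) stop("series too short: need at least 100 points")
  half <- series[(n %/% 2 + 1):n]
  mu2 <- mean(half)
  if (var(half) == 0) {
    sd2 <- 0
    tau <- 0.5
  } else {
    sd2 <- sd(half)
    tau <- tryCatch(dl_integrated_autocorr_time(half)$tau_int,
                    error = function(e) 0.5)
  }
  tail_len <- n - seq_len(n) + 1
  tail_mean <- rev(cumsum(rev(series))) / tail_len
  n_eff <- pmax(1, tail_len / (2 * tau))
  se <- sd2 / sqrt(n_eff)
  ok <- abs(tail_mean - mu2) <= 2 * se + 1e-12
  # tails with fewer than ~10 effective samples carry no usable signal
  ok[tail_len < 20 * tau] <- TRUE
  bad <- which(!ok)
  if (length(bad) == 0L) return(0L)
  max(bad)
}
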