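#' Model parameters for the dynamic looping mechanism
#'
#' @param cutoff Maximum genomic (along-chain) separation, in monomers, at
#'   which a cross-link may form; sets the maximum loop size.  Must be >= 2.
#' @param p_form Per-candidate-pair, per-sweep probability of forming a
#'   cross-link, in \[0, 1\].  The stationary loop concentration is an
#'   emergent observable of `(p_form, lifetime)`; use [dl_calibrate_p()] to
#'   target a given concentration.
#' @param lifetime Mean cross-link lifetime, in sweeps.  Each new link lives
#'   `1 + Poisson(lifetime)` sweeps.
#' @param max_links Maximum number of simultaneous cross-links per monomer.
#' @param force Constant stretching force, in kT per lattice unit, applied
#'   to the end monomers along the end-to-end vector (0 = no pulling).
#' @return A list of class `dl_params`.
#' @export
dl_params <- function(cutoff = 50L, p_form = 0, lifetime = 100, max_links = 4L,
                      force = 0) {
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 2L) stop("cutoff must be an integer >= 2")
  if (!is.finite(p_form) || p_form < 0 || p_form > 1)
    stop("p_form must be in [0, 1]")
  if (!is.finite(lifetime) || lifetime < 1) stop("lifetime must be >= 1 sweep")
  max_links <- as.integer(max_links)
  if (is.na(max_links) || max_links < 1L) stop("max_links must be >= 1")
  if (!is.finite(force) || force < 0) stop("force must be >= 0")
  structure(list(cutoff = cutoff, p_form = p_form, lifetime = lifetime,
                 max_links = max_links, force = force),
            class = "dl_params")
}

#' @export
print.dl_params <- function(x, ...) {
  cat(sprintf(
    "<dl_params> cutoff %d, p_form %.4g, lifetime %g sweeps, max_links %d, force %g kT/l.u.\n",
    x$cutoff, x$p_form, x$lifetime, x$max_links, x$force))
  invisible(x)
}

cpp_params <- function(params, conf) {
  c(unclass(params), list(box = conf$box))
}

#' Cross-link candidate pairs
#'
#' All unordered monomer pairs (i, j) that could form a cross-link right
#' now: genomic separation `2 <= j - i <= cutoff`, current displacement in
#' the allowed bond set ("physical proximity"), pair not already linked and
#' both monomers below `max_links`.  Pairs are returned in ascending (i, j)
#' order.
#'
#' @param conf A `dl_conformation`.
#' @param params A `dl_params`.
#' @return Integer matrix with columns `i`, `j` (possibly zero rows).
#' @export
dl_find_candidates <- function(conf, params) {
  stopifnot(inherits(conf, "dl_conformation"), inherits(params, "dl_params"))
  cpp_find_candidates(conf$positions, conf$links, cpp_params(params, conf))
}

#' Stochastic cross-link formation
#'
#' Scans candidate pairs in ascending (i, j) order; each forms a link
#' independently with probability `p_form`.  A new link expires at
#' `sweep + 1 + Poisson(lifetime)`, so every link lives at least one sweep.
#' Links formed earlier in the scan count towards `max_links` for later
#' pairs.
#'
#' @param conf A `dl_conformation`.
#' @param params A `dl_params`.
#' @param seed Integer seed for the engine RNG.
#' @return The conformation with any newly formed links added.
#' @export
dl_attempt_link_formation <- function(conf, params, seed = 1L) {
  stopifnot(inherits(conf, "dl_conformation"), inherits(params, "dl_params"))
  links <- cpp_attempt_links(conf$positions, conf$links, conf$sweep,
                             cpp_params(params, conf), as.integer(seed))
  conf$links <- links
  conf
}

#' Dissolve expired cross-links
#'
#' Removes every link with `expiry <= sweep` (a link whose expiry equals
#' the current sweep counter is dissolved).
#'
#' @param conf A `dl_conformation`.
#' @return The conformation with expired links removed.
#' @export
dl_expire_links <- function(conf) {
  stopifnot(inherits(conf, "dl_conformation"))
  keep <- conf$links[, "expiry"] > conf$sweep
  conf$links <- conf$links[keep, , drop = FALSE]
  conf
}

#' Loop concentration of a conformation
#'
#' Number of active cross-links divided by the chain length N.
#'
#' @param conf A `dl_conformation`.
#' @return A single number (0 when there are no links).
#' @export
dl_loop_concentration <- function(conf) {
  stopifnot(inherits(conf, "dl_conformation"))
  nrow(conf$links) / nrow(conf$positions)
}

#' Loop-size histogram over an ensemble
#'
#' Counts active cross-links by genomic size `j - i` over sizes
#' `2 .. cutoff`, averaged per conformation.
#'
#' @param conformations A list of `dl_conformation` objects (or a single
#'   one).
#' @param cutoff Maximum loop size (upper edge of the histogram).
#' @return A data frame with columns `size` and `count` (mean count per
#'   conformation).
#' @export
dl_loop_size_histogram <- function(conformations, cutoff) {
  if (inherits(conformations, "dl_conformation"))
    conformations <- list(conformations)
  if (length(conformations) < 1L) stop("need at least one conformation")
  cutoff <- as.integer(cutoff)
  sizes <- 2:cutoff
  acc <- numeric(length(sizes))
  for (conf in conformations) {
    if (nrow(conf$links) > 0L) {
      s <- conf$links[, "j"] - conf$links[, "i"]
      acc <- acc + tabulate(s - 1L, nbins = cutoff - 1L)
    }
  }
  data.frame(size = sizes, count = acc / length(conformations))
}

#' Calibrate the formation probability to a target loop concentration
#'
#' The stationary loop concentration is a monotone non-decreasing function
#' of `p_form` at fixed lifetime, so a bisection on pilot runs recovers the
#' probability that realizes a requested concentration.  Each pilot run
#' equilibrates a self-avoiding chain, switches the looping mechanism on,
#' discards a burn-in and averages the link count over the remainder.
#'
#' @param target Target stationary loop concentration (links per monomer),
#'   in `(0, max_links / 2]`.
#' @param n_monomers Chain length used for the pilot runs.
#' @param params A `dl_params`; its `p_form` is ignored.
#' @param tol Relative tolerance on the achieved concentration (default 5%).
#' @param pilot_sweeps Sweeps per pilot run after the loops-on switch; the
#'   first half is discarded as burn-in.
#' @param saw_sweeps Loops-off equilibration sweeps before each pilot.
#' @param max_iter Maximum bisection steps.
#' @param seed Integer seed; all pilot runs use sub-seeds derived from it.
#' @param start Optional pre-equilibrated self-avoiding `dl_conformation`
#'   to start the pilots from (skips the loops-off stage).
#' @return The calibrated probability, with attributes `achieved` (the
#'   pilot-run concentration) and `iterations`.  If the target exceeds the
#'   achievable ceiling at `p_form = 1`, the ceiling is reported in the
#'   error message.
#' @export
dl_calibrate_p <- function(target, n_monomers, params, tol = 0.05,
                           pilot_sweeps = 20000, saw_sweeps = 5000,
                           max_iter = 12L, seed = 1L, start = NULL) {
  stopifnot(inherits(params, "dl_params"))
  if (target == 0) return(structure(0, achieved = 0, iterations = 0L))
  if (target < 0 || target > params$max_links / 2)
    stop("target must lie in (0, max_links/2]")
  seeds <- dl_derive_seeds(seed, 2L + max_iter)

  if (is.null(start)) {
    base <- dl_init_chain(n_monomers)
    saw <- dl_advance(base, dl_params(cutoff = params$cutoff), saw_sweeps,
                      seed = seeds[1])$conf
  } else {
    stopifnot(inherits(start, "dl_conformation"))
    saw <- start
  }

  pilot <- function(p) {
    pp <- params
    pp$p_form <- p
    pp$force <- 0
    out <- dl_advance(saw, pp, pilot_sweeps, seed = seeds[2])
    burn <- seq_len(floor(pilot_sweeps / 2))
    mean(out$n_links[-burn]) / n_monomers
  }

  hi_conc <- pilot(1)
  if (hi_conc < target * (1 - tol))
    stop(sprintf(
      "target concentration %.3g unreachable: ceiling at p_form = 1 is %.3g",
      target, hi_conc))
  # always bisect at least once so the smallest probability realizing the
  # target is preferred (p_form = 1 can sit near the target through
  # jamming while much smaller probabilities reach it in the fluid branch)
  lo <- 0; hi <- 1; p <- 1; achieved <- hi_conc; it <- 0L
  for (k in seq_len(max_iter)) {
    if (k > 1L && abs(achieved - target) <= tol * target) break
    p <- (lo + hi) / 2
    achieved <- pilot(p)
    it <- k
    if (achieved < target) lo <- p else hi <- p
  }
  structure(p, achieved = achieved, iterations = it)
}
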