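as_positions <- function(x) {
  if (inherits(x, "dl_conformation")) return(x$positions)
  m <- as.matrix(x)
  if (ncol(m) != 3L) stop("positions must have 3 columns")
  m
}

new_backbone <- function(points, m, mode) {
  structure(list(points = points, m = as.integer(m), mode = mode),
            class = "dl_backbone")
}

#' @export
print.dl_backbone <- function(x, ...) {
  cat(sprintf("<dl_backbone> %s, level m = %d, %d point(s)\n",
              x$mode, x$m, nrow(x$points)))
  invisible(x)
}

#' Coarse-grained backbone (disjoint blocks)
#'
#' The chain is divided into consecutive disjoint sections of `m` monomers
#' and each section is replaced by its center of mass; the resulting
#' polyline approximates the chromatid axis at coarse-graining level `m`.
#' A trailing remainder of fewer than `m` monomers is dropped.
#'
#' @param conf A `dl_conformation` or a numeric N x 3 position matrix.
#' @param m Monomers per block (1 <= m <= N).
#' @return A `dl_backbone` with `floor(N/m)` points.
#' @export
dl_coarse_backbone <- function(conf, m) {
  pos <- as_positions(conf)
  n <- nrow(pos)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (m > n) stop("m exceeds the number of monomers")
  nb <- n %/% m
  idx <- rep(seq_len(nb), each = m)
  pts <- rowsum(pos[seq_len(nb * m), , drop = FALSE] + 0, idx) / m
  new_backbone(unname(pts), m, "coarse")
}

#' Smooth backbone (sliding window)
#'
#' Sliding-window centers of mass with stride 1: point k is the center of
#' mass of monomers `k .. k+m-1`, giving `N - m + 1` closely spaced points
#' that form a nearly smooth axis trajectory.
#'
#' @inheritParams dl_coarse_backbone
#' @return A `dl_backbone` with `N - m + 1` points.
#' @export
dl_smooth_backbone <- function(conf, m) {
  pos <- as_positions(conf)
  n <- nrow(pos)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (m > n) stop("m exceeds the number of monomers")
  cs <- apply(pos, 2, function(v) cumsum(as.numeric(v)))
  cs <- rbind(0, cs)
  pts <- (cs[(m + 1L):(n + 1L), , drop = FALSE] -
            cs[1:(n - m + 1L), , drop = FALSE]) / m
  new_backbone(unname(pts), m, "smooth")
}

backbone_points <- function(x) {
  if (inherits(x, "dl_backbone")) x$points else as_positions(x)
}

# Per-conformation mean dot product of unit bond vectors at each arc
# separation s = 0 .. nb-1 (nb = number of backbone bonds).
dl_k_profile <- function(points) {
  b <- diff(points)
  len <- sqrt(rowSums(b^2))
  if (any(len == 0)) stop("degenerate (zero-length) backbone bond")
  u <- b / len
  nb <- nrow(u)
  g <- tcrossprod(u)   # g[i, j] = u_i . u_j
  vapply(0:(nb - 1L), function(s) {
    i <- seq_len(nb - s)
    mean(g[cbind(i, i + s)])
  }, numeric(1))
}

#' Mean directional correlation of an ensemble of backbones
#'
#' For each conformation the directional correlation at arc separation `s`
#' is the average over all backbone positions of the dot product of unit
#' bond vectors `s` bonds apart; the profile is then averaged over the
#' ensemble, with the standard error across conformations.
#'
#' @param backbones A `dl_backbone` or a list of them (all with the same
#'   number of points, >= 3).
#' @return An object of class `dl_correlation`: a data frame with columns
#'   `s`, `K` and `stderr`, plus attributes `ensemble_size` and
#'   `mean_bond_length`.
#' @export
dl_directional_correlation <- function(backbones) {
  if (inherits(backbones, "dl_backbone")) backbones <- list(backbones)
  if (length(backbones) < 1L) stop("need at least one backbone")
  pts <- lapply(backbones, backbone_points)
  if (any(vapply(pts, nrow, 1L) < 3L)) stop("backbones need at least 3 points")
  if (length(unique(vapply(pts, nrow, 1L))) != 1L)
    stop("all backbones must have the same number of points")
  ks <- vapply(pts, dl_k_profile, numeric(nrow(pts[[1]]) - 1L))
  ks <- matrix(ks, ncol = length(pts))
  bl <- mean(vapply(pts, function(p) mean(sqrt(rowSums(diff(p)^2))), 1))
  K <- rowMeans(ks)
  se <- if (ncol(ks) > 1L) apply(ks, 1, sd) / sqrt(ncol(ks)) else rep(NA_real_, nrow(ks))
  out <- data.frame(s = 0:(nrow(ks) - 1L), K = K, stderr = se)
  attr(out, "ensemble_size") <- length(pts)
  attr(out, "mean_bond_length") <- bl
  class(out) <- c("dl_correlation", "data.frame")
  out
}

#' Persistence length from a directional-correlation profile
#'
#' The integral width of the correlation function: trapezoid-rule integral
#' of `K(s)` over arc length, truncated at the first non-positive `K`
#' value (which suppresses the noise-dominated tail), converted to lattice
#' units with the mean backbone bond length.  An exponential fit
#' `K(s) = exp(-s/s0)` over the decaying range is returned as an
#' independent cross-check.
#'
#' @param profile A `dl_correlation` (or data frame with columns `s`, `K`).
#' @param mean_bond_length Mean backbone bond length in lattice units;
#'   defaults to the attribute carried by the profile.
#' @return A list with `lp` (trapezoid estimate, lattice units), `lp_exp`
#'   (exponential-fit estimate, `NA` when no fit is possible),
#'   `truncated_at` (first non-positive lag, `NA` if none) and `rod_like`
#'   (`TRUE` when `K` never decays below 0.99: the profile only yields a
#'   lower bound and `lp` is reported as `Inf`).
#' @export
dl_persistence_length <- function(profile, mean_bond_length = NULL) {
  if (is.null(mean_bond_length))
    mean_bond_length <- attr(profile, "mean_bond_length")
  if (is.null(mean_bond_length))
    stop("mean_bond_length is required")
  s <- profile$s
  K <- profile$K
  if (abs(K[1]) > 1 + 1e-9 || abs(K[1] - 1) > 1e-9)
    stop("profile must start at K(0) = 1")
  if (all(K > 0.99)) {
    return(list(lp = Inf, lp_exp = NA_real_, truncated_at = NA_integer_,
                rod_like = TRUE))
  }
  bad <- which(K <= 0)
  cut <- if (length(bad) > 0L) bad[1L] else length(K)
  ss <- s[1:cut]
  kk <- K[1:cut]
  lp <- sum(diff(ss) * (head(kk, -1) + tail(kk, -1)) / 2) * mean_bond_length
  dec <- which(K > 0.01 & s >= 1)
  dec <- dec[dec <= cut]
  lp_exp <- NA_real_
  if (length(dec) >= 2L) {
    fit <- lm(log(K[dec]) ~ s[dec])
    sl <- coef(fit)[2]
    if (is.finite(sl) && sl < 0) lp_exp <- -1 / sl * mean_bond_length
  }
  list(lp = unname(lp), lp_exp = unname(lp_exp),
       truncated_at = if (length(bad) > 0L) bad[1L] - 1L else NA_integer_,
       rod_like = FALSE)
}

#' Select the coarse-graining level by exponential-fit quality
#'
#' At a well-chosen coarse-graining level the backbone behaves like a
#' worm-like chain: the directional correlation decays exponentially.  Too
#' little coarse graining leaves local coiling in the profile, too much
#' destroys the decay.  For each candidate level this routine fits
#' `log K(s)` linearly over the decaying range and returns the level with
#' the highest coefficient of determination (ties towards smaller `m`).
#'
#' @param conformations List of conformations (or position matrices).
#' @param candidate_levels Integer vector of candidate `m` values.
#' @return The selected level, with attribute `fits` (data frame of level,
#'   r-squared and decay length).  Errors if every candidate level gives a
#'   degenerate fit (no decaying range), e.g. for an ensemble of rods.
#' @export
dl_select_coarse_level <- function(conformations, candidate_levels) {
  if (inherits(conformations, "dl_conformation"))
    conformations <- list(conformations)
  candidate_levels <- sort(unique(as.integer(candidate_levels)))
  if (length(candidate_levels) < 1L) stop("need at least one candidate level")
  n_mono <- nrow(as_positions(conformations[[1]]))
  rows <- lapply(candidate_levels, function(m) {
    # levels leaving fewer than 9 backbone points cannot support a fit
    if (n_mono %/% m < 9L)
      return(data.frame(m = m, r2 = NA_real_, s0 = NA_real_))
    prof <- tryCatch(
      dl_directional_correlation(
        lapply(conformations, dl_coarse_backbone, m = m)),
      error = function(e) NULL)
    if (is.null(prof)) return(data.frame(m = m, r2 = NA_real_, s0 = NA_real_))
    K <- prof$K; s <- prof$s
    # fit only the well-resolved part of the decay; the far tail is noise
    bad <- which(K <= 0.1)
    cut <- if (length(bad) > 0L) bad[1L] - 1L else length(K)
    use <- which(s >= 1 & seq_along(K) <= cut)
    if (length(use) < 3L || K[2] > 0.995)   # no decay to fit
      return(data.frame(m = m, r2 = NA_real_, s0 = NA_real_))
    fit <- lm(log(K[use]) ~ s[use])
    sl <- coef(fit)[2]
    if (!is.finite(sl) || sl >= 0)
      return(data.frame(m = m, r2 = NA_real_, s0 = NA_real_))
    data.frame(m = m, r2 = summary(fit)$r.squared, s0 = -1 / sl)
  })
  fits <- do.call(rbind, rows)
  if (all(is.na(fits$r2)))
    stop("degenerate fits at every candidate level (no exponential decay)")
  best <- fits$m[which.max(fits$r2)]
  structure(best, fits = fits)
}

#' Contour length of a backbone
#'
#' Sum of consecutive point-to-point distances of the backbone polyline
#' (the chromatid length when applied to a smooth backbone).
#'
#' @param backbone A `dl_backbone` (or point matrix).
#' @return Length in lattice units (0 for a single point).
#' @export
dl_chromatid_length <- function(backbone) {
  pts <- backbone_points(backbone)
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Lengthwise compaction ratio of an ensemble
#'
#' Contour length of the unlooped fibre, `(N - 1)` times the mean
#' monomer-bond length, divided by the mean smooth-backbone contour length
#' of the condensed conformations.
#'
#' @param conformations List of `dl_conformation` objects.
#' @param m Coarse-graining level for the smooth backbones.
#' @return The dimensionless fold-compaction (1 for a straight rod).
#' @export
dl_compaction_ratio <- function(conformations, m) {
  if (inherits(conformations, "dl_conformation"))
    conformations <- list(conformations)
  bond_len <- mean(vapply(conformations, function(conf) {
    mean(sqrt(rowSums(diff(as_positions(conf))^2)))
  }, 1))
  n <- nrow(as_positions(conformations[[1]]))
  axis_len <- mean(vapply(conformations, function(conf) {
    dl_chromatid_length(dl_smooth_backbone(conf, m))
  }, 1))
  if (axis_len == 0) stop("zero backbone length")
  (n - 1) * bond_len / axis_len
}

# Distance from each point to the nearest segment of a polyline.
dl_perp_distances <- function(positions, backbone) {
  P <- as_positions(positions) + 0
  B <- backbone_points(backbone)
  if (nrow(B) < 2L) stop("backbone needs at least 2 points")
  best <- rep(Inf, nrow(P))
  for (k in seq_len(nrow(B) - 1L)) {
    a <- B[k, ]
    ab <- B[k + 1L, ] - a
    ab2 <- sum(ab^2)
    ap <- sweep(P, 2, a)
    t <- if (ab2 == 0) rep(0, nrow(P)) else pmin(1, pmax(0, (ap %*% ab) / ab2))
    d2 <- rowSums((ap - outer(as.numeric(t), ab))^2)
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Radial monomer density about the backbone
#'
#' For every monomer the perpendicular distance is its distance to the
#' nearest point of the smooth-backbone polyline (closest-segment
#' projection).  Counts are binned in `r` and normalized by the
#' cylindrical shell volume `2 pi r dr L`, with `L` the backbone contour
#' length, so integrating `density x shell volume` recovers N exactly.
#'
#' @param conf A `dl_conformation` (or position matrix).
#' @param backbone A smooth `dl_backbone` for the same conformation.
#' @param bin_width Radial bin width in lattice units.
#' @return An object of class `dl_radial_density`: data frame with columns
#'   `r_lo`, `r_hi`, `r_mid`, `count`, `density`; attributes
#'   `backbone_length` and `n_monomers`.
#' @export
dl_radial_density <- function(conf, backbone, bin_width = 1) {
  d <- dl_perp_distances(conf, backbone)
  L <- dl_chromatid_length(backbone)
  if (L == 0) stop("zero-length backbone")
  nb <- max(1L, ceiling(max(d) / bin_width + 1e-9))
  edges <- bin_width * (0:nb)
  idx <- pmin(nb, floor(d / bin_width) + 1L)
  count <- tabulate(idx, nbins = nb)
  r_mid <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
                    r_mid = r_mid, count = count,
                    density = count / (2 * pi * r_mid * bin_width * L))
  attr(out, "backbone_length") <- L
  attr(out, "n_monomers") <- length(d)
  class(out) <- c("dl_radial_density", "data.frame")
  out
}

#' Chromatid thickness
#'
#' The radius within which a fraction `theta` of all monomers lie, i.e.
#' the `theta`-quantile (inverse empirical CDF) of the perpendicular
#' distances to the smooth backbone.
#'
#' @inheritParams dl_radial_density
#' @param theta Quantile in (0, 1]; default 0.90.
#' @return Radius in lattice units.
#' @export
dl_thickness <- function(conf, backbone, theta = 0.9) {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  d <- dl_perp_distances(conf, backbone)
  unname(quantile(d, theta, type = 1))
}
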