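#' Reconstruction targets
#'
#' Target statistics for point-pattern reconstruction: a nearest-neighbour
#' (NN) distance histogram on fixed bins, an optional radial
#' (distance-to-myofibril) histogram, an optional axial histogram, a hard-core
#' minimum spacing, and per-statistic weights. Histograms are proportions
#' (sum 1). A truncated-normal NN target can be requested by giving `nn_mean`
#' and `nn_sd` instead of an explicit histogram; distances beyond the last
#' break are folded into the last bin.
#'
#' @param n_points number of points to place (>= 2).
#' @param nn_mean,nn_sd mean and sd (um) of a normal NN-distance law,
#'   truncated below at `min_spacing`.
#' @param nn_target explicit NN histogram (proportions, one per bin).
#' @param nn_breaks NN histogram breaks (um); default 0-2 um in 0.05 um bins.
#' @param radial_target optional radial histogram (proportions).
#' @param radial_breaks radial breaks (um); default 0-0.7 um in 0.05 um bins.
#' @param axial_target optional axial histogram; the default point mass at 0
#'   encodes z-disc confinement after snapping.
#' @param min_spacing hard-core distance (um); default 0.2, the confocal
#'   resolution limit.
#' @param weights named weights for `G`, `radial` and `axial` energy terms.
#' @return an object of class `ryr_targets`.
#' @export
reconstruction_targets <- function(n_points, nn_mean = NULL, nn_sd = NULL,
                                   nn_target = NULL,
                                   nn_breaks = seq(0, 2, by = 0.05),
                                   radial_target = NULL,
                                   radial_breaks = seq(0, 0.7, by = 0.05),
                                   axial_target = NULL,
                                   min_spacing = 0.2,
                                   weights = c(G = 1, radial = 1, axial = 0)) {
  if (n_points < 2) abort("n_points must be >= 2")
  if (min_spacing < 0) abort("min_spacing must be >= 0")
  if (is.null(nn_target)) {
    if (is.null(nn_mean) || is.null(nn_sd))
      abort("give either nn_target or nn_mean and nn_sd")
    nn_target <- truncnorm_bin_probs(nn_breaks, nn_mean, nn_sd, min_spacing)
  }
  if (abs(sum(nn_target) - 1) > 1e-8) abort("nn_target must sum to 1")
  if (length(nn_target) != length(nn_breaks) - 1)
    abort("nn_target length must match nn_breaks")
  if (!is.null(radial_target)) {
    if (abs(sum(radial_target) - 1) > 1e-8)
      abort("radial_target must sum to 1")
    if (length(radial_target) != length(radial_breaks) - 1)
      abort("radial_target length must match radial_breaks")
  }
  w <- c(G = 1, radial = 1, axial = 0)
  w[names(weights)] <- weights
  if (any(w < 0)) abort("weights must be non-negative")
  if (is.null(radial_target)) w["radial"] <- 0
  structure(list(n_points = as.integer(n_points),
                 nn_breaks = nn_breaks, nn_target = nn_target,
                 radial_breaks = radial_breaks, radial_target = radial_target,
                 axial_target = axial_target,
                 min_spacing = min_spacing, weights = w,
                 nn_mean = nn_mean, nn_sd = nn_sd),
            class = "ryr_targets")
}

# bin probabilities of Normal(mean, sd) truncated to (lower, Inf), with the
# upper tail folded into the last bin
truncnorm_bin_probs <- function(breaks, mean, sd, lower) {
  lo <- pmax(breaks[-length(breaks)], lower)
  hi <- pmax(breaks[-1], lower)
  p <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  p[length(p)] <- p[length(p)] + (1 - pnorm(max(hi[length(hi)], lower), mean, sd))
  p / sum(p)
}

#' @export
print.ryr_targets <- function(x, ...) {
  cat(sprintf(
    "<ryr_targets: n = %d, min_spacing = %.2f um, weights G=%g radial=%g>\n",
    x$n_points, x$min_spacing, x$weights["G"], x$weights["radial"]))
  invisible(x)
}

# histogram proportions of values on breaks, overflow folded into last bin
hist_props <- function(v, breaks) {
  dr <- breaks[2] - breaks[1]
  nb <- length(breaks) - 1
  b <- pmin(nb, floor(v / dr) + 1)
  tabulate(b, nbins = nb) / length(v)
}

#' Measure reconstruction targets from an observed pattern
#'
#' Computes the NN-distance, radial and axial target histograms and the point
#' count from an observed pattern, mirroring what the reconstruction consumes.
#'
#' @param pattern an observed point pattern (>= 2 points).
#' @param volume the `label_volume` (or window) supplying the myofibril
#'   distance transform.
#' @param planes z-disc planes (um).
#' @inheritParams reconstruction_targets
#' @export
measure_targets <- function(pattern, volume, planes,
                            nn_breaks = seq(0, 2, by = 0.05),
                            radial_breaks = seq(0, 0.7, by = 0.05),
                            min_spacing = 0.2,
                            weights = c(G = 1, radial = 1, axial = 0)) {
  if (nrow(pattern) < 2) abort("need at least 2 points")
  prof <- distance_profile(pattern, volume, planes)
  nnd <- nn_distances(pattern)
  reconstruction_targets(
    n_points = nrow(pattern),
    nn_target = hist_props(nnd, nn_breaks), nn_breaks = nn_breaks,
    radial_target = hist_props(prof$distances$radial, radial_breaks),
    radial_breaks = radial_breaks,
    axial_target = hist_props(prof$distances$axial, radial_breaks),
    min_spacing = min_spacing, weights = weights)
}

#' Reconstruction energy of a pattern
#'
#' The energy is the weighted sum of squared bin-wise discrepancies between
#' the pattern's current histograms (as proportions) and the targets:
#' `E = w_G * sum_b (G_t(b) - G_c(b))^2 + w_rad * sum_b (R_t(b) - R_c(b))^2
#' + w_ax * sum_b (A_t(b) - A_c(b))^2`. A pattern whose statistics equal the
#' targets has zero energy.
#'
#' @param pattern a point pattern with `targets$n_points` points.
#' @param targets an `ryr_targets`.
#' @param window an `ryr_window` carrying `dist_myo` (needed when the radial
#'   weight is positive).
#' @param planes z-disc planes (needed when the axial weight is positive).
#' @return non-negative scalar.
#' @export
pattern_energy <- function(pattern, targets, window = NULL, planes = NULL) {
  if (nrow(pattern) != targets$n_points)
    abort("pattern size does not match targets$n_points")
  w <- targets$weights
  e <- 0
  if (w["G"] > 0) {
    cur <- hist_props(nn_distances(pattern), targets$nn_breaks)
    e <- e + w["G"] * sum((targets$nn_target - cur)^2)
  }
  if (w["radial"] > 0) {
    if (is.null(window) || is.null(window$dist_myo))
      abort("radial energy needs a window with a myofibril distance transform")
    m <- as.matrix(pattern[, c("x", "y", "z")])
    idx <- voxel_index_of(list(labels = window$mask,
                               voxel_size = window$voxel_size), m)
    rad <- window$dist_myo[idx]
    cur <- hist_props(rad, targets$radial_breaks)
    e <- e + w["radial"] * sum((targets$radial_target - cur)^2)
  }
  if (w["axial"] > 0) {
    if (is.null(planes)) abort("axial energy needs z-disc planes")
    ax <- vapply(pattern$z, function(a) min(abs(planes - a)), numeric(1))
    cur <- hist_props(ax, targets$radial_breaks)
    e <- e + w["axial"] * sum((targets$axial_target - cur)^2)
  }
  unname(e)
}

#' Reconstruct a point pattern matching target statistics
#'
#' Places `targets$n_points` points inside the admissible window, snapped to
#' the z-disc planes, so that their NN-distance (and optionally radial)
#' histograms match the targets. The pattern is initialised by CSR inside the
#' window and refined by single-point relocation proposals accepted greedily
#' (or by simulated annealing), the classical energy-minimisation
#' reconstruction of point-process statistics.
#'
#' @param targets an `ryr_targets`.
#' @param window an `ryr_window` built by [build_window()].
#' @param planes z-disc plane positions (um).
#' @param seed RNG seed.
#' @param max_iter maximum number of proposals.
#' @param tol stop when the energy drops to this value.
#' @param anneal `NULL` for greedy descent, or `list(temp0 =, cool =)` for a
#'   geometric annealing schedule.
#' @param max_consec_rej hard failure after this many consecutive
#'   min-spacing rejections (infeasible window).
#' @return an object of class `ryr_recon`: `pattern`, `energy`,
#'   `energy_trace`, `iterations`, `accepted`, `converged`, `audit_max`.
#' @export
reconstruct <- function(targets, window, planes, seed = 1,
                        max_iter = 2e5, tol = 1e-4, anneal = NULL,
                        max_consec_rej = 1e4) {
  if (window$type != "mask") abort("reconstruction needs a mask window")
  if (length(planes) < 1) abort("need at least one z-disc plane")
  d <- dim(window$mask)
  h <- window$voxel_size
  zc <- (seq_len(d[3]) - 0.5) * h[3]
  # admissible voxels restricted to the slices nearest each z-disc plane
  slices <- unique(vapply(planes, function(p) which.min(abs(zc - p)),
                          integer(1)))
  plane_of_slice <- vapply(slices, function(s)
    planes[which.min(abs(planes - zc[s]))], numeric(1))
  adm <- list(x = numeric(0), y = numeric(0), z = numeric(0), rad = numeric(0))
  for (si in seq_along(slices)) {
    sl <- slices[si]
    w2 <- which(window$mask[, , sl], arr.ind = TRUE)
    if (is.null(dim(w2))) w2 <- matrix(w2, ncol = 2)
    adm$x <- c(adm$x, (w2[, 1] - 0.5) * h[1])
    adm$y <- c(adm$y, (w2[, 2] - 0.5) * h[2])
    adm$z <- c(adm$z, rep(plane_of_slice[si], nrow(w2)))
    adm$rad <- c(adm$rad, window$dist_myo[cbind(w2, sl)])
  }
  if (length(adm$x) < targets$n_points)
    abort("window admits fewer voxels than n_points on the z-disc planes")
  w <- targets$weights
  r_target <- targets$radial_target
  if (is.null(r_target)) r_target <- rep(0, length(targets$radial_breaks) - 1)
  temp0 <- if (is.null(anneal)) 0 else anneal$temp0
  cool <- if (is.null(anneal)) 1 else anneal$cool
  set.seed(seed)
  res <- reconstruct_cpp(adm$x, adm$y, adm$z, adm$rad,
                         jitter = h[1:2], n_points = targets$n_points,
                         g_dr = diff(targets$nn_breaks)[1],
                         g_target = targets$nn_target,
                         r_dr = diff(targets$radial_breaks)[1],
                         r_target = r_target,
                         w_g = unname(w["G"]), w_rad = unname(w["radial"]),
                         min_spacing = targets$min_spacing,
                         max_iter = as.integer(max_iter), tol = tol,
                         temp0 = temp0, cool = cool,
                         max_consec_rej = as.integer(max_consec_rej))
  if (res$status == 1)
    abort("could not initialise: min_spacing infeasible in this window")
  if (res$status == 2)
    abort("reconstruction stalled: too many consecutive min-spacing rejections")
  structure(list(pattern = ryr_pattern(res$points),
                 energy = res$energy, energy_trace = res$trace,
                 iterations = res$iterations, accepted = res$accepted,
                 converged = res$converged, audit_max = res$audit_max,
                 targets = targets, seed = seed),
            class = "ryr_recon")
}

#' @export
print.ryr_recon <- function(x, ...) {
  cat(sprintf(
    "<ryr_recon: %d points, E = %.3g after %d proposals (%d accepted)%s>\n",
    nrow(x$pattern), x$energy, x$iterations, as.integer(x$accepted),
    if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Validate an observed pattern against reconstruction targets
#'
#' Simulates `n_sims` reconstructions from the targets, builds min/max
#' envelopes for the requested statistics and reports whether the observed
#' curves stay inside — the acceptance logic used to validate that a target
#' set of statistics suffices to recapitulate the observed organisation.
#'
#' @param observed the observed point pattern.
#' @param targets an `ryr_targets`.
#' @param window,planes as for [reconstruct()].
#' @param n_sims number of reconstructions (99 by convention).
#' @param statistics subset of F/G/K/PCF.
#' @param r_grid radii (um).
#' @param seed master seed.
#' @param ... passed to [reconstruct()] (e.g. `max_iter`).
#' @return an `ryr_envelopes` object.
#' @export
validate_against <- function(observed, targets, window, planes, n_sims = 99,
                             statistics = c("F", "G", "K", "PCF"),
                             r_grid = seq(0, 2, by = 0.05), seed = 1, ...) {
  sim <- function(s) reconstruct(targets, window, planes, seed = s, ...)$pattern
  envelope_test(observed, sim, n_sims = n_sims, statistics = statistics,
                r_grid = r_grid, window = window, seed = seed)
}

#' Species presets for RyR cluster distributions
#'
#' Rat: cluster count from the measured couplon density of 1.3 per um^2 of
#' cross-section, NN distance 0.59 +/- 0.16 um, 2 pA release current per
#' cluster. Human: clusters are ~40% fewer (87 on the reference 94.8 um^2
#' cross-section, scaled proportionally for other areas), NN mean 0.79 um,
#' and the per-cluster current is raised to conserve the total release
#' (2 pA x n_rat / n_human, i.e. 2.8 pA on the reference template).
#'
#' @param name `"rat"` or `"human"`.
#' @param cross_section_area template cross-section area (um^2).
#' @param nn_sd NN-distance spread (um); the human preset reuses the rat
#'   spread as only the mean shift is reported.
#' @return a list: `species`, `n`, `current_pA`, `targets` (an
#'   `ryr_targets`), `nn_mean`, `nn_sd`.
#' @export
species_presets <- function(name = c("rat", "human"),
                            cross_section_area = 94.8, nn_sd = 0.16) {
  name <- match.arg(name)
  if (cross_section_area <= 0) abort("area must be positive")
  n_rat <- floor(1.3 * cross_section_area)
  if (name == "rat") {
    n <- n_rat
    nn_mean <- 0.59
    current <- 2
  } else {
    n <- max(2L, round(87 * cross_section_area / 94.8))
    nn_mean <- 0.79
    current <- 2 * n_rat / n
  }
  list(species = name, n = as.integer(n), current_pA = current,
       nn_mean = nn_mean, nn_sd = nn_sd,
       targets = reconstruction_targets(n, nn_mean = nn_mean, nn_sd = nn_sd))
}
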