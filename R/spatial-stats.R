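#' Summary-function curves
#'
#' Summary curves are tibbles with columns `r` (um) and `value`, of class
#' `ryr_curve`, carrying the statistic name ("F", "G", "K" or "PCF") and
#' estimation metadata as attributes.
#'
#' @name ryr_curve
NULL

new_curve <- function(r, value, statistic, ...) {
  out <- tibble(r = as.numeric(r), value = as.numeric(value))
  attr(out, "statistic") <- statistic
  meta <- list(...)
  if (length(meta)) attr(out, "meta") <- meta
  class(out) <- c("ryr_curve", class(out))
  out
}

#' @export
print.ryr_curve <- function(x, ...) {
  cat(sprintf("<ryr_curve: %s on %d radii in [%.3g, %.3g] um>\n",
              attr(x, "statistic"), nrow(x), min(x$r), max(x$r)))
  NextMethod()
}

check_r_grid <- function(r_grid) {
  if (length(r_grid) < 1 || any(r_grid < 0) || any(diff(r_grid) <= 0))
    abort("r_grid must be non-negative and strictly increasing")
  r_grid
}

#' Nearest-neighbour distance distribution function G
#'
#' `G(r)` is the empirical CDF of nearest-neighbour distances: the fraction of
#' points whose nearest neighbour lies within distance `r`. No edge correction
#' is applied by default (observed and null-model curves share the same bias in
#' envelope tests); a reduced-sample border correction is available.
#'
#' @param pattern a point pattern with at least 2 points.
#' @param r_grid radii (um), strictly increasing.
#' @param correction `"none"` (default) or `"border"`.
#' @param window required for `correction = "border"`.
#' @return an `ryr_curve` for statistic "G".
#' @export
estimate_G <- function(pattern, r_grid, correction = c("none", "border"),
                       window = NULL) {
  correction <- match.arg(correction)
  check_r_grid(r_grid)
  if (nrow(pattern) < 2) abort("G requires at least 2 points")
  nnd <- nn_distances(pattern)
  if (correction == "none") {
    v <- vapply(r_grid, function(r) mean(nnd <= r), numeric(1))
  } else {
    if (is.null(window)) abort("border correction needs a window")
    b <- window_boundary_distance(window, as.matrix(pattern[, c("x", "y", "z")]))
    v <- vapply(r_grid, function(r) {
      keep <- b >= r
      if (!any(keep)) return(NA_real_)
      mean(nnd[keep] <= r)
    }, numeric(1))
  }
  new_curve(r_grid, v, "G", correction = correction)
}

#' Empty-space function F
#'
#' `F(r)` is the probability that the distance from an arbitrary location of
#' the admissible window to the nearest point of the pattern is at most `r`.
#' Test locations are a fixed seeded lattice of admissible voxels jittered
#' uniformly within each voxel, so estimates are reproducible.
#'
#' @param pattern a non-empty point pattern.
#' @param window an `ryr_window`.
#' @param r_grid radii (um).
#' @param n_test_points number of test locations (>= 100).
#' @param seed RNG seed for the jitter.
#' @param correction `"none"` (default) or `"border"` (reduced sample: at
#'   radius r only test locations at least r from the window boundary count,
#'   which removes the edge bias entirely for box windows).
#' @return an `ryr_curve` for statistic "F".
#' @export
estimate_F <- function(pattern, window, r_grid, n_test_points = 10000,
                       seed = 1, correction = c("none", "border")) {
  correction <- match.arg(correction)
  check_r_grid(r_grid)
  if (nrow(pattern) < 1) abort("F requires a non-empty pattern")
  if (n_test_points < 100) abort("n_test_points must be >= 100")
  set.seed(seed)
  u <- window_test_points(window, n_test_points)
  dmin <- min_dist_to_pattern(u, pattern)
  if (correction == "none") {
    v <- vapply(r_grid, function(r) mean(dmin <= r), numeric(1))
  } else {
    b <- window_boundary_distance(window, u)
    v <- vapply(r_grid, function(r) {
      keep <- b >= r
      if (!any(keep)) return(NA_real_)
      mean(dmin[keep] <= r)
    }, numeric(1))
  }
  new_curve(r_grid, v, "F", n_test_points = nrow(u), seed = seed,
            correction = correction)
}

# minimum distance from each row of u (m x 3) to the pattern, chunked to
# bound memory
min_dist_to_pattern <- function(u, pattern) {
  p <- as.matrix(pattern[, c("x", "y", "z")])
  m <- nrow(u)
  out <- numeric(m)
  chunk <- max(1L, floor(2e6 / nrow(p)))
  for (s in seq(1, m, by = chunk)) {
    e <- min(m, s + chunk - 1)
    uu <- u[s:e, , drop = FALSE]
    d2 <- outer(rowSums(uu^2), rep(1, nrow(p))) +
      outer(rep(1, nrow(uu)), rowSums(p^2)) - 2 * uu %*% t(p)
    out[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Ripley's K function
#'
#' `K(r)` is the mean number of further points within distance `r` of a point
#' of the pattern, divided by the intensity `lambda = n / |W|`. No edge
#' correction is applied by default; a reduced-sample border correction is
#' available.
#'
#' @inheritParams estimate_G
#' @param window an `ryr_window` (supplies the admissible volume for lambda).
#' @return an `ryr_curve` for statistic "K" with attribute `lambda`.
#' @export
estimate_K <- function(pattern, window, r_grid,
                       correction = c("none", "border")) {
  correction <- match.arg(correction)
  check_r_grid(r_grid)
  if (nrow(pattern) < 2) abort("K requires at least 2 points")
  lambda <- pattern_intensity(pattern, window)
  d <- as.matrix(dist(as.matrix(pattern[, c("x", "y", "z")])))
  diag(d) <- Inf
  if (correction == "none") {
    v <- vapply(r_grid, function(r) mean(rowSums(d <= r)) / lambda,
                numeric(1))
  } else {
    b <- window_boundary_distance(window, as.matrix(pattern[, c("x", "y", "z")]))
    v <- vapply(r_grid, function(r) {
      keep <- b >= r
      if (!any(keep)) return(NA_real_)
      mean(rowSums(d[keep, , drop = FALSE] <= r)) / lambda
    }, numeric(1))
  }
  out <- new_curve(r_grid, v, "K", correction = correction, lambda = lambda)
  out
}

#' Pair correlation function from a K curve
#'
#' Numerically differentiates a K estimate (moving-average smoothing followed
#' by centered finite differences) and normalises by the derivative of the
#' Poisson K: `2 pi r` in 2D or `4 pi r^2` in 3D. The value at `r = 0` is
#' excluded (set to `NA`).
#'
#' @param k_curve an `ryr_curve` of statistic "K" with >= 5 radii.
#' @param dimension 2 or 3; selects the CSR normalisation.
#' @param smoothing_window moving-average width (radii) applied to K before
#'   differencing.
#' @return an `ryr_curve` for statistic "PCF".
#' @export
estimate_pcf <- function(k_curve, dimension = 3, smoothing_window = 5) {
  if (!inherits(k_curve, "ryr_curve") || attr(k_curve, "statistic") != "K")
    abort("estimate_pcf needs a K curve")
  if (nrow(k_curve) < 5) abort("need at least 5 radii")
  if (!dimension %in% c(2, 3)) abort("dimension must be 2 or 3")
  r <- k_curve$r
  k <- k_curve$value
  if (smoothing_window > 1) {
    w <- rep(1 / smoothing_window, smoothing_window)
    ks <- as.numeric(stats::filter(k, w, sides = 2))
    ks[is.na(ks)] <- k[is.na(ks)]  # ends keep the raw values
  } else ks <- k
  n <- length(r)
  dk <- numeric(n)
  dk[2:(n - 1)] <- (ks[3:n] - ks[1:(n - 2)]) / (r[3:n] - r[1:(n - 2)])
  dk[1] <- (ks[2] - ks[1]) / (r[2] - r[1])
  dk[n] <- (ks[n] - ks[n - 1]) / (r[n] - r[n - 1])
  denom <- if (dimension == 2) 2 * pi * r else 4 * pi * r^2
  g <- ifelse(r > 0, dk / denom, NA_real_)
  new_curve(r, g, "PCF", dimension = dimension,
            smoothing_window = smoothing_window,
            derivative = "centered finite differences on moving-average-smoothed K")
}

#' Simulate complete spatial randomness in a window
#'
#' Draws `n_points` locations uniformly over the admissible region (uniform
#' voxel choice jittered within the voxel for mask windows).
#'
#' @param window an `ryr_window`.
#' @param n_points number of points.
#' @param seed RNG seed.
#' @export
simulate_csr <- function(window, n_points, seed = NULL) {
  if (window$type == "mask" && length(window$idx) < n_points)
    abort("window has fewer admissible voxels than requested points")
  if (!is.null(seed)) set.seed(seed)
  ryr_pattern(window_runif(window, n_points))
}

#' Monte-Carlo envelope test of a point-process model
#'
#' Simulates `n_sims` patterns from a null model, estimates the requested
#' summary functions for each, and forms pointwise minimum/maximum envelopes.
#' The observed pattern is judged "outside" for a statistic if its curve exits
#' the envelope at any radius.
#'
#' @param observed the observed point pattern.
#' @param null_simulator `function(seed)` returning a point pattern drawn from
#'   the null model.
#' @param n_sims number of simulations (>= 19; 99 by convention).
#' @param statistics subset of `c("F", "G", "K", "PCF")`.
#' @param r_grid radii (um).
#' @param window an `ryr_window`; required for "F", "K" and "PCF".
#' @param seed master seed; per-simulation seeds are derived from it.
#' @param pcf_dimension 2, 3 or `NULL` (choose by pattern dimensionality:
#'   planar patterns use the 2D normalisation).
#' @param f_test_points test locations for "F".
#' @return An object of class `ryr_envelopes`: a named list of `ryr_envelope`
#'   tibbles (`r`, `lower`, `observed`, `upper`) with a per-statistic verdict;
#'   see [tidy.ryr_envelopes()].
#' @export
envelope_test <- function(observed, null_simulator, n_sims = 99,
                          statistics = c("F", "G", "K", "PCF"),
                          r_grid, window = NULL, seed = 1,
                          pcf_dimension = NULL, f_test_points = 2000) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (n_sims < 19) abort("n_sims must be >= 19")
  if (is.null(window) && any(statistics %in% c("F", "K", "PCF")))
    abort("F, K and PCF need a window")
  check_r_grid(r_grid)
  if (is.null(pcf_dimension)) pcf_dimension <- pattern_dim(observed)

  curves_of <- function(pat) {
    out <- list()
    if ("G" %in% statistics) out$G <- estimate_G(pat, r_grid)
    if ("F" %in% statistics)
      out$F <- estimate_F(pat, window, r_grid, n_test_points = f_test_points,
                          seed = seed)
    if (any(c("K", "PCF") %in% statistics)) {
      k <- estimate_K(pat, window, r_grid)
      if ("K" %in% statistics) out$K <- k
      if ("PCF" %in% statistics)
        out$PCF <- estimate_pcf(k, dimension = pcf_dimension)
    }
    out
  }

  obs <- curves_of(observed)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  sims <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    pat <- null_simulator(sim_seeds[s])
    if (nrow(pat) < 2)
      abort(sprintf("null simulator returned %d point(s) at replicate %d",
                    nrow(pat), s))
    sims[[s]] <- curves_of(pat)
  }

  envs <- lapply(statistics, function(st) {
    mat <- vapply(sims, function(cv) cv[[st]]$value, numeric(length(r_grid)))
    lower <- apply(mat, 1, min, na.rm = TRUE)
    upper <- apply(mat, 1, max, na.rm = TRUE)
    obsv <- obs[[st]]$value
    ok <- is.finite(obsv) & is.finite(lower) & is.finite(upper)
    outside <- any(obsv[ok] < lower[ok] | obsv[ok] > upper[ok])
    env <- tibble(r = r_grid, lower = lower, observed = obsv, upper = upper)
    attr(env, "statistic") <- st
    attr(env, "n_sims") <- n_sims
    attr(env, "verdict") <- if (outside) "outside" else "inside"
    class(env) <- c("ryr_envelope", class(env))
    env
  })
  names(envs) <- statistics
  structure(envs, class = "ryr_envelopes", seed = seed)
}

#' Verdicts of an envelope test
#' @param envelopes an `ryr_envelopes` object.
#' @return named character vector, "inside" or "outside" per statistic.
#' @export
envelope_verdicts <- function(envelopes) {
  vapply(envelopes, function(e) attr(e, "verdict"), character(1))
}

#' @export
print.ryr_envelopes <- function(x, ...) {
  v <- envelope_verdicts(x)
  cat(sprintf("<ryr_envelopes: %s>\n",
              paste(sprintf("%s=%s", names(v), v), collapse = ", ")))
  invisible(x)
}

#' Curve and envelope CSV export
#'
#' Curves use the header `r_um,value`; envelopes `r_um,lower,observed,upper`.
#' @param x an `ryr_curve` or `ryr_envelope`.
#' @param path file path.
#' @export
write_curve <- function(x, path) {
  if (inherits(x, "ryr_envelope")) {
    df <- data.frame(r_um = x$r, lower = x$lower, observed = x$observed,
                     upper = x$upper)
  } else {
    df <- data.frame(r_um = x$r, value = x$value)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
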