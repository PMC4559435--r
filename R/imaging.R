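#' Normalised fluorescence F/F0
#'
#' Divides a Fluo-4-bound-Ca field by its resting baseline. Mitochondria
#' voxels (which carry no dye) are set to 0.
#'
#' @param x an `ryr_sim`, a 3D field array, or a 2D slice matrix.
#' @param baseline resting bound-dye concentration (uM); taken from the
#'   simulation when `x` is an `ryr_sim`.
#' @param volume needed to zero mitochondria when `x` is an array.
#' @return array/matrix of F/F0 values (mitochondria 0).
#' @export
f_over_f0 <- function(x, baseline = NULL, volume = NULL) {
  if (inherits(x, "ryr_sim")) {
    arr <- sim_field(x, names(x$state$bound)[1], fill = 0)
    return(arr / x$f4ca0)
  }
  if (is.null(baseline) || baseline <= 0)
    abort("baseline must be a positive resting concentration")
  out <- x / baseline
  if (!is.null(volume)) out[volume$labels == LBL_MITO] <- 0
  out[is.na(out)] <- 0
  out
}

#' Confocal point-spread-function specification
#'
#' Gaussian PSF stand-in for a measured confocal kernel.
#'
#' @param fwhm_lateral,fwhm_axial full widths at half maximum (um).
#' @param truncate kernel truncation radius in sigmas.
#' @export
psf_spec <- function(fwhm_lateral = 0.25, fwhm_axial = 0.6, truncate = 3) {
  if (fwhm_lateral <= 0 || fwhm_axial <= 0) abort("FWHMs must be positive")
  structure(list(fwhm_lateral = fwhm_lateral, fwhm_axial = fwhm_axial,
                 truncate = truncate), class = "psf_spec")
}

# separable Gaussian blur of a matrix with reflecting boundaries
gaussian_blur <- function(mat, sigma_px, truncate = 3) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(truncate * sigma_px))
  k <- exp(-0.5 * ((-r:r) / sigma_px)^2)
  k <- k / sum(k)
  conv1 <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[pmin(n, r:1), , drop = FALSE], m,
                 m[pmax(1, n - 0:(r - 1)), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1) + seq_len(n), ,
                                                    drop = FALSE]
    out
  }
  t(conv1(t(conv1(mat))))
}

# block-average downsampling; conserves the mean of full blocks exactly
block_mean <- function(mat, f) {
  if (f <= 1) return(mat)
  n1 <- (nrow(mat) %/% f) * f
  n2 <- (ncol(mat) %/% f) * f
  m <- mat[seq_len(n1), seq_len(n2), drop = FALSE]
  a <- array(m, c(f, n1 / f, n2))
  m2 <- colMeans(a)               # (n1/f) x n2
  a2 <- array(t(m2), c(f, n2 / f, n1 / f))
  t(colMeans(a2))
}

#' Render a confocal view of a model image
#'
#' Convolves the model image with a Gaussian PSF, block-averages down to the
#' acquisition pixel pitch (0.02 um model pixels scaled down 10x to 0.2 um by
#' default), and applies Poisson noise `I' = Poisson(s I) / s` with photon
#' scale `s`.
#'
#' @param image 2D matrix of model intensities (non-negative).
#' @param pixel_size model pixel size (um).
#' @param psf a [psf_spec()]; `NULL` for no blur.
#' @param downsample integer block factor (>= 1).
#' @param photon_scale photons per intensity unit; `Inf` for noise-free.
#' @param seed RNG seed for the noise.
#' @return a list: `image` (rendered matrix), `pixel_size` (um).
#' @export
render_confocal <- function(image, pixel_size, psf = psf_spec(),
                            downsample = 10, photon_scale = 100,
                            seed = NULL) {
  if (downsample < 1) abort("downsample must be >= 1")
  img <- image
  img[is.na(img)] <- 0
  if (!is.null(psf)) {
    sigma_px <- psf$fwhm_lateral / (2 * sqrt(2 * log(2))) / pixel_size
    img <- gaussian_blur(img, sigma_px, psf$truncate)
  }
  img <- block_mean(img, as.integer(downsample))
  if (is.finite(photon_scale)) {
    if (!is.null(seed)) set.seed(seed)
    img <- matrix(rpois(length(img), photon_scale * pmax(0, img)),
                  nrow(img)) / photon_scale
  }
  list(image = img, pixel_size = pixel_size * downsample)
}

#' Intensity profile along a line
#'
#' Bilinear interpolation of a 2D image along the segment
#' `(x0, y0) -> (x1, y1)`, optionally averaged over a perpendicular band of
#' the given width.
#'
#' @param image 2D matrix; rows index x, columns y (voxel-center convention).
#' @param pixel_size pixel size (um).
#' @param line `c(x0, y0, x1, y1)` in um.
#' @param width band width (um); 0 = single line.
#' @param step sampling step (um); defaults to the pixel size.
#' @return tibble with `position` (um along the line) and `value`.
#' @export
line_profile <- function(image, pixel_size, line, width = 0, step = NULL) {
  stopifnot(length(line) == 4)
  p0 <- line[1:2]; p1 <- line[3:4]
  L <- sqrt(sum((p1 - p0)^2))
  if (L <= 0) abort("degenerate line")
  if (is.null(step)) step <- pixel_size
  pos <- seq(0, L, by = step)
  dir <- (p1 - p0) / L
  nrm <- c(-dir[2], dir[1])
  offs <- if (width > 0) seq(-width / 2, width / 2, by = pixel_size) else 0
  interp <- function(x, y) {
    fx <- x / pixel_size - 0.5
    fy <- y / pixel_size - 0.5
    i0 <- pmin(nrow(image) - 1, pmax(1, floor(fx) + 1))
    j0 <- pmin(ncol(image) - 1, pmax(1, floor(fy) + 1))
    tx <- pmin(1, pmax(0, fx + 1 - i0))
    ty <- pmin(1, pmax(0, fy + 1 - j0))
    v00 <- image[cbind(i0, j0)]
    v10 <- image[cbind(i0 + 1, j0)]
    v01 <- image[cbind(i0, j0 + 1)]
    v11 <- image[cbind(i0 + 1, j0 + 1)]
    (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
      (1 - tx) * ty * v01 + tx * ty * v11
  }
  vals <- rowMeans(vapply(offs, function(o) {
    x <- p0[1] + pos * dir[1] + o * nrm[1]
    y <- p0[2] + pos * dir[2] + o * nrm[2]
    interp(x, y)
  }, numeric(length(pos))))
  tibble(position = pos, value = vals)
}

#' Local cluster density along a line
#'
#' Counts clusters within a spherical neighbourhood (default radius 1 um)
#' centred at sample positions along the line and divides by the sphere
#' volume.
#'
#' @param pattern a point pattern.
#' @param line `c(x0, y0, x1, y1)` (um); the line lives at axial position `z`.
#' @param z axial position of the line (um).
#' @param radius neighbourhood radius (um).
#' @param step sampling step (um).
#' @return tibble with `position` and `density` (um^-3).
#' @export
cluster_density_profile <- function(pattern, line, z = 0, radius = 1,
                                    step = 0.1) {
  if (nrow(pattern) < 1) abort("pattern is empty")
  p0 <- line[1:2]; p1 <- line[3:4]
  L <- sqrt(sum((p1 - p0)^2))
  pos <- seq(0, L, by = step)
  dir <- (p1 - p0) / L
  vol <- 4 / 3 * pi * radius^3
  m <- as.matrix(pattern[, c("x", "y", "z")])
  dens <- vapply(pos, function(s) {
    c0 <- c(p0 + s * dir, z)
    sum((m[, 1] - c0[1])^2 + (m[, 2] - c0[2])^2 +
          (m[, 3] - c0[3])^2 <= radius^2) / vol
  }, numeric(1))
  tibble(position = pos, density = dens)
}

#' Spatial heterogeneity metrics of a field
#'
#' Minimum, maximum, mean, coefficient of variation and fold-range
#' (max / min) over the masked voxels.
#'
#' @param field numeric array.
#' @param mask logical array of the same shape (e.g. cytosol voxels).
#' @return one-row tibble.
#' @export
heterogeneity_metrics <- function(field, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(field) else as.numeric(field[mask])
  v <- v[is.finite(v)]
  if (length(v) == 0) abort("mask selects no finite voxels")
  tibble(min = min(v), max = max(v), mean = mean(v), sd = sd(v),
         cv = sd(v) / mean(v),
         fold_range = max(v) / max(min(v), .Machine$double.eps))
}

#' Build a line scan from a simulation
#'
#' Takes the plane snapshots recorded by [simulate_transient()]
#' (`record_slice`), converts them to F/F0, renders each frame through the
#' confocal pipeline, and extracts the profile along the scan line for every
#' recorded time.
#'
#' @param sim an `ryr_sim` run with `record_slice`.
#' @param line `c(x0, y0, x1, y1)` (um) within the recorded plane.
#' @param psf a [psf_spec()] (or `NULL` for the raw model view).
#' @param downsample block factor for the rendered view.
#' @param photon_scale Poisson photon scale (`Inf` = noise-free).
#' @param seed noise seed.
#' @return an `ryr_linescan` tibble: `time`, `position`, `model` (raw F/F0)
#'   and `rendered` (confocal view).
#' @export
line_scan <- function(sim, line, psf = psf_spec(), downsample = 2,
                      photon_scale = 100, seed = 1) {
  if (is.null(sim$snapshots))
    abort("simulation was run without record_slice; no plane snapshots")
  h <- sim$domain$voxel_size[1]
  mito <- is.na(sim$snapshots[[1]])
  out <- vector("list", length(sim$snapshots))
  for (k in seq_along(sim$snapshots)) {
    f <- sim$snapshots[[k]] / sim$f4ca0
    f[mito] <- 0
    raw <- line_profile(f, h, line)
    ren <- render_confocal(f, h, psf = psf, downsample = downsample,
                           photon_scale = photon_scale, seed = seed + k)
    renp <- line_profile(ren$image, ren$pixel_size, line)
    out[[k]] <- tibble(time = sim$record_times[k],
                       position = raw$position,
                       model = raw$value,
                       rendered = approx(renp$position, renp$value,
                                         xout = raw$position,
                                         rule = 2)$y)
  }
  res <- bind_rows(out)
  class(res) <- c("ryr_linescan", class(res))
  attr(res, "line") <- line
  res
}
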