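#' Labelled voxel volumes
#'
#' A `label_volume` wraps a 3D integer array of voxel labels (0 = cytosol /
#' background, 1 = myofibril, 2 = mitochondria) together with the physical
#' voxel size. Coordinates follow the voxel-center convention: the center of
#' voxel `(i, j, k)` (1-based indices) lies at `(i - 0.5) * dx` etc., with the
#' origin at the corner of the first voxel. The axial (long-cell) axis is the
#' third array dimension by default.
#'
#' @param labels 3D integer array with values in {0, 1, 2}.
#' @param voxel_size voxel edge length (um); scalar or length-3 `(dx, dy, dz)`.
#' @param axial_axis which array dimension runs along the cell's long axis.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, axial_axis = 3L) {
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1L)
  if (length(dim(labels)) != 3) abort("labels must be a 3D array")
  if (!all(labels %in% c(LBL_CYTO, LBL_MYO, LBL_MITO)))
    abort("labels must be 0 (cytosol), 1 (myofibril) or 2 (mitochondria)")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (any(voxel_size <= 0)) abort("voxel_size must be positive")
  structure(
    list(labels = array(as.integer(labels), dim(labels)),
         voxel_size = as.numeric(voxel_size),
         axial_axis = as.integer(axial_axis)),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  fr <- label_fractions(x)
  cat(sprintf(
    "<label_volume: %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um>\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  cytosol %.1f%% | myofibril %.1f%% | mitochondria %.1f%%\n",
              100 * fr["cytosol"], 100 * fr["myofibril"],
              100 * fr["mitochondria"]))
  invisible(x)
}

#' Label area/volume fractions of a volume
#' @param volume a `label_volume`.
#' @export
label_fractions <- function(volume) {
  l <- volume$labels
  n <- length(l)
  c(cytosol = sum(l == LBL_CYTO) / n,
    myofibril = sum(l == LBL_MYO) / n,
    mitochondria = sum(l == LBL_MITO) / n)
}

# voxel-center coordinates along one array dimension
axis_coords <- function(volume, axis) {
  (seq_len(dim(volume$labels)[axis]) - 0.5) * volume$voxel_size[axis]
}

# physical extents (um) of the volume
volume_extent <- function(volume) dim(volume$labels) * volume$voxel_size

# nearest voxel index (1-based, clamped) for physical coordinates; m is an
# n x 3 matrix of coordinates
voxel_index_of <- function(volume, m) {
  d <- dim(volume$labels)
  idx <- sapply(1:3, function(a)
    pmin(d[a], pmax(1L, as.integer(ceiling(m[, a] / volume$voxel_size[a])))))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  idx
}

#' Distance transform to a label class
#'
#' Exact Euclidean distance (um) from every voxel center to the nearest voxel
#' center carrying `label`, computed with a separable lower-envelope distance
#' transform that honours anisotropic voxel sizes.
#'
#' @param volume a `label_volume`.
#' @param label the target label (default myofibril, 1).
#' @return 3D numeric array of distances (um).
#' @export
distance_to_label <- function(volume, label = LBL_MYO) {
  feat <- volume$labels == label
  if (!any(feat)) abort("volume contains no voxel with the requested label")
  d <- edt3d_cpp(as.logical(feat), dim(volume$labels), volume$voxel_size)
  array(d, dim(volume$labels))
}

#' Read and write label volumes as multi-page TIFF
#'
#' One page per axial slice, 8-bit, with integer labels {0, 1, 2}. The voxel
#' size is stored in a YAML sidecar `<path>.yaml` (`voxel_size_um`).
#'
#' @param path TIFF file path.
#' @param voxel_size voxel size (um); when `NULL` the YAML sidecar is read.
#' @export
read_label_volume <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(round(pages[[k]]))
  if (is.null(voxel_size)) {
    side <- paste0(path, ".yaml")
    if (!file.exists(side)) abort("voxel_size not given and no YAML sidecar found")
    voxel_size <- yaml::read_yaml(side)$voxel_size_um
  }
  label_volume(arr, voxel_size)
}

#' @rdname read_label_volume
#' @param volume a `label_volume`.
#' @export
write_label_volume <- function(volume, path) {
  d <- dim(volume$labels)
  pages <- lapply(seq_len(d[3]), function(k)
    matrix(volume$labels[, , k] / 255, d[1], d[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  yaml::write_yaml(list(voxel_size_um = volume$voxel_size),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Observation windows for point patterns
#'
#' An `ryr_window` is either a rectangular box (all space admissible) or a
#' voxel mask derived from a [label_volume] (see [build_window()]). It carries
#' everything the estimators need: the admissible measure, uniform sampling of
#' locations, and quasi-random test points.
#'
#' @param extent box edge lengths `(lx, ly, lz)` in um.
#' @param voxel_size nominal voxel size used when a voxelised view is needed.
#' @export
box_window <- function(extent, voxel_size = 0.1) {
  stopifnot(length(extent) == 3, all(extent > 0))
  structure(list(type = "box", extent = as.numeric(extent),
                 voxel_size = rep(voxel_size, 3)),
            class = "ryr_window")
}

# internal constructor for mask windows
mask_window <- function(mask, voxel_size, dist_myo = NULL, axial_axis = 3L,
                        max_radial = NA_real_) {
  structure(list(type = "mask", mask = mask, voxel_size = voxel_size,
                 dist_myo = dist_myo, axial_axis = axial_axis,
                 max_radial = max_radial,
                 idx = which(mask)),
            class = "ryr_window")
}

#' @export
print.ryr_window <- function(x, ...) {
  if (x$type == "box") {
    cat(sprintf("<ryr_window: box %.3g x %.3g x %.3g um>\n",
                x$extent[1], x$extent[2], x$extent[3]))
  } else {
    cat(sprintf("<ryr_window: mask, %d admissible voxels (%.3g um^3)>\n",
                length(x$idx), window_volume(x)))
  }
  invisible(x)
}

#' Admissible volume of a window (um^3)
#' @param window an `ryr_window`.
#' @export
window_volume <- function(window) {
  if (window$type == "box") prod(window$extent)
  else length(window$idx) * prod(window$voxel_size)
}

# is each point (n x 3 matrix) inside the admissible region?
window_contains <- function(window, m) {
  if (window$type == "box") {
    apply(m, 1, function(p) all(p >= 0 & p <= window$extent))
  } else {
    d <- dim(window$mask)
    idx <- sapply(1:3, function(a)
      as.integer(ceiling(m[, a] / window$voxel_size[a])))
    if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
    inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
      idx[, 2] >= 1 & idx[, 2] <= d[2] &
      idx[, 3] >= 1 & idx[, 3] <= d[3]
    out <- rep(FALSE, nrow(m))
    if (any(inside))
      out[inside] <- window$mask[cbind(idx[inside, 1, drop = FALSE],
                                       idx[inside, 2, drop = FALSE],
                                       idx[inside, 3, drop = FALSE])]
    out
  }
}

# draw n uniform locations in the admissible region (uses the current RNG
# stream); voxel windows sample a voxel then jitter within it
window_runif <- function(window, n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  if (window$type == "box") {
    cbind(runif(n, 0, window$extent[1]),
          runif(n, 0, window$extent[2]),
          runif(n, 0, window$extent[3]))
  } else {
    pick <- window$idx[sample.int(length(window$idx), n, replace = TRUE)]
    ai <- arrayInd(pick, dim(window$mask))
    h <- window$voxel_size
    cbind((ai[, 1] - 1 + runif(n)) * h[1],
          (ai[, 2] - 1 + runif(n)) * h[2],
          (ai[, 3] - 1 + runif(n)) * h[3])
  }
}

# approximately n quasi-random test locations: an evenly strided lattice of
# admissible voxels, jittered uniformly within each voxel
window_test_points <- function(window, n) {
  if (window$type == "box") {
    m <- max(1L, floor(n^(1 / 3)))
    g <- expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m))
    h <- window$extent / m
    cbind((g$i - 1 + runif(nrow(g))) * h[1],
          (g$j - 1 + runif(nrow(g))) * h[2],
          (g$k - 1 + runif(nrow(g))) * h[3])
  } else {
    stride <- max(1L, floor(length(window$idx) / n))
    pick <- window$idx[seq(1, length(window$idx), by = stride)]
    ai <- arrayInd(pick, dim(window$mask))
    h <- window$voxel_size
    nn <- nrow(ai)
    cbind((ai[, 1] - 1 + runif(nn)) * h[1],
          (ai[, 2] - 1 + runif(nn)) * h[2],
          (ai[, 3] - 1 + runif(nn)) * h[3])
  }
}

# distance from points (n x 3) to the window boundary (for border correction)
window_boundary_distance <- function(window, m) {
  if (window$type == "box") {
    apply(m, 1, function(p) min(p, window$extent - p))
  } else {
    # distance to the nearest non-admissible voxel center
    d <- edt3d_cpp(as.logical(!window$mask), dim(window$mask),
                   window$voxel_size)
    arr <- array(d, dim(window$mask))
    idx <- voxel_index_of(list(labels = window$mask,
                               voxel_size = window$voxel_size), m)
    arr[idx]
  }
}
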