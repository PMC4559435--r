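#' Identify z-disc planes from a point pattern
#'
#' RyR clusters aggregate at z-discs, so planes are found as local maxima of
#' the axial point-count histogram. Candidate peaks are taken in decreasing
#' count order subject to a minimum mutual separation, then refined as the mean
#' axial coordinate of the points within `min_separation / 2` of the peak bin.
#'
#' @param pattern a non-empty point pattern.
#' @param axial_axis coordinate used as the axial direction (1, 2 or 3).
#' @param min_separation minimum separation between detected planes (um);
#'   default 0.5, half of the half-sarcomere.
#' @param bin_width histogram bin (um); use the axial voxel size.
#' @return numeric vector of plane positions (um), ascending.
#' @export
identify_zdiscs <- function(pattern, axial_axis = 3L, min_separation = 0.5,
                            bin_width = 0.05) {
  if (nrow(pattern) < 1) abort("pattern is empty")
  ax <- as.matrix(pattern[, c("x", "y", "z")])[, axial_axis]
  if (diff(range(ax)) < bin_width)
    return(mean(ax))
  breaks <- seq(floor(min(ax) / bin_width) * bin_width,
                max(ax) + bin_width, by = bin_width)
  cnt <- graphics::hist(ax, breaks = breaks, plot = FALSE)$counts
  mids <- breaks[-length(breaks)] + bin_width / 2
  # local maxima (>= both neighbours)
  n <- length(cnt)
  left <- c(-1, cnt[-n])
  right <- c(cnt[-1], -1)
  cand <- which(cnt > 0 & cnt >= left & cnt >= right)
  cand <- cand[order(cnt[cand], decreasing = TRUE)]
  sel <- numeric(0)
  for (b in cand) {
    if (all(abs(mids[b] - sel) >= min_separation)) sel <- c(sel, mids[b])
  }
  planes <- vapply(sel, function(p) {
    near <- abs(ax - p) <= min_separation / 2
    mean(ax[near])
  }, numeric(1))
  sort(planes)
}

#' Snap points to the nearest z-disc plane
#'
#' Replaces each point's axial coordinate with the nearest plane; transverse
#' coordinates are unchanged. The operation is idempotent.
#'
#' @param pattern a point pattern.
#' @param planes plane positions (um), non-empty.
#' @param axial_axis axial coordinate (1, 2 or 3).
#' @export
snap_to_zdiscs <- function(pattern, planes, axial_axis = 3L) {
  if (length(planes) < 1) abort("planes must be non-empty")
  m <- as.matrix(pattern[, c("x", "y", "z")])
  nearest <- vapply(m[, axial_axis], function(a)
    planes[which.min(abs(planes - a))], numeric(1))
  m[, axial_axis] <- nearest
  ryr_pattern(m)
}

#' Build the admissible window W
#'
#' The admissible window holds the voxels in which RyR clusters may live:
#' cytosolic (background) voxels whose Euclidean distance to the nearest
#' myofibril voxel center is at most `max_radial` (0.7 um by default).
#' Mitochondria voxels are never admissible.
#'
#' @param volume a `label_volume` with at least one myofibril and one
#'   non-myofibril voxel.
#' @param max_radial maximal distance to the myofibril set (um).
#' @return an `ryr_window` (mask type) that also carries the myofibril
#'   distance transform for later radial statistics.
#' @export
build_window <- function(volume, max_radial = 0.7) {
  l <- volume$labels
  if (!any(l == LBL_MYO)) abort("volume has no myofibril voxel")
  if (all(l == LBL_MYO)) abort("volume is all myofibril")
  dmyo <- distance_to_label(volume, LBL_MYO)
  mask <- l == LBL_CYTO & dmyo <= max_radial + 1e-9
  mask_window(mask, volume$voxel_size, dist_myo = dmyo,
              axial_axis = volume$axial_axis, max_radial = max_radial)
}

#' Radial and axial distance profile of a pattern
#'
#' Per point: the radial distance to the nearest myofibril voxel (via the
#' distance transform) and the axial distance to the nearest z-disc plane.
#'
#' @param pattern a point pattern.
#' @param volume a `label_volume` (or an `ryr_window` built from one).
#' @param planes z-disc plane positions (um).
#' @param bin_width histogram bin (um).
#' @return a list with `distances` (tibble: point, radial, axial),
#'   `radial_hist` and `axial_hist` (tibbles: mid, count).
#' @export
distance_profile <- function(pattern, volume, planes, bin_width = 0.05) {
  if (inherits(volume, "ryr_window")) {
    dmyo <- volume$dist_myo
    vs <- volume$voxel_size
    dims <- dim(volume$mask)
  } else {
    dmyo <- distance_to_label(volume, LBL_MYO)
    vs <- volume$voxel_size
    dims <- dim(volume$labels)
  }
  m <- as.matrix(pattern[, c("x", "y", "z")])
  idx <- sapply(1:3, function(a)
    pmin(dims[a], pmax(1L, as.integer(ceiling(m[, a] / vs[a])))))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  radial <- dmyo[idx]
  ax <- m[, 3]
  axial <- vapply(ax, function(a) min(abs(planes - a)), numeric(1))
  hist_of <- function(v) {
    breaks <- seq(0, max(v, bin_width) + bin_width, by = bin_width)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    tibble(mid = h$mids, count = h$counts)
  }
  list(distances = tibble(point = seq_len(nrow(m)), radial = radial,
                          axial = axial),
       radial_hist = hist_of(radial),
       axial_hist = hist_of(axial))
}

#' Extrude a thin section into a half-sarcomere stack
#'
#' Replicates the section's slices by reflective tiling along the axial axis
#' (mirror continuation at each section boundary) until the stack is at least
#' `target_depth` deep, then crops to `target_depth`. Transverse labels are
#' unchanged, so per-slice area fractions are preserved exactly.
#'
#' @param section a `label_volume` whose depth is at most `target_depth`.
#' @param target_depth desired axial depth (um); default the 0.9 um
#'   half-sarcomere.
#' @export
extrude_half_sarcomere <- function(section, target_depth = 0.9) {
  dz <- section$voxel_size[3]
  k <- dim(section$labels)[3]
  depth <- k * dz
  n_target <- round(target_depth / dz)
  if (n_target < k) abort("target_depth is smaller than the section depth")
  if (n_target == k) return(section)
  base <- c(seq_len(k), rev(seq_len(k)))
  order <- rep_len(base, n_target)
  label_volume(section$labels[, , order, drop = FALSE], section$voxel_size,
               axial_axis = section$axial_axis)
}

#' Mark Ca release-site voxels around cluster centroids
#'
#' For each cluster centroid, collects the voxels of the diffusive domain
#' whose centers lie within `radius` (default 0.1 um, i.e. a 200 nm diameter
#' release sphere) and reports the realised voxel-sum volume.
#'
#' @param pattern cluster centroids (all inside the volume).
#' @param volume a `label_volume`.
#' @param radius release-sphere radius (um).
#' @param eligible `"domain"` (cytosol + myofibril voxels, the diffusive
#'   domain) or `"cytosol"` (background label only).
#' @return an object of class `ryr_sites`: a list with one element per
#'   cluster (`cluster_id`, `center`, `voxels` as linear indices into the
#'   label array, `volume_um3`, `latency`, `active`). Empty sites trigger a
#'   warning and are marked inactive.
#' @export
mark_release_sites <- function(pattern, volume, radius = 0.1,
                               eligible = c("domain", "cytosol")) {
  eligible <- match.arg(eligible)
  d <- dim(volume$labels)
  h <- volume$voxel_size
  ext <- d * h
  m <- as.matrix(pattern[, c("x", "y", "z")])
  if (any(m < 0) || any(m[, 1] > ext[1]) || any(m[, 2] > ext[2]) ||
      any(m[, 3] > ext[3]))
    abort("all cluster centroids must lie inside the volume")
  ok_label <- if (eligible == "domain") c(LBL_CYTO, LBL_MYO) else LBL_CYTO
  sites <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    ctr <- m[i, ]
    lo <- pmax(1L, as.integer(floor((ctr - radius) / h)) + 1L)
    hi <- pmin(d, as.integer(ceiling((ctr + radius) / h)))
    if (any(lo > hi)) { vox <- integer(0) } else {
      g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
      cx <- (g$i - 0.5) * h[1]
      cy <- (g$j - 0.5) * h[2]
      cz <- (g$k - 0.5) * h[3]
      within <- (cx - ctr[1])^2 + (cy - ctr[2])^2 + (cz - ctr[3])^2 <= radius^2
      lin <- g$i + (g$j - 1L) * d[1] + (g$k - 1L) * d[1] * d[2]
      vox <- lin[within & (volume$labels[lin] %in% ok_label)]
    }
    if (length(vox) == 0)
      warn(sprintf("cluster %d has no eligible release voxel; site is empty",
                   i))
    sites[[i]] <- list(cluster_id = i, center = ctr, voxels = vox,
                       volume_um3 = length(vox) * prod(h),
                       latency = 0, active = length(vox) > 0)
  }
  structure(sites, class = "ryr_sites", radius = radius)
}

#' @export
print.ryr_sites <- function(x, ...) {
  vols <- vapply(x, function(s) s$volume_um3, numeric(1))
  cat(sprintf(
    "<ryr_sites: %d sites (%d active), mean realised volume %.3g um^3>\n",
    length(x), sum(vapply(x, function(s) s$active, logical(1))), mean(vols)))
  invisible(x)
}
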