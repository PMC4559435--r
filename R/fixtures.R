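#' Synthetic template specification
#'
#' Describes a synthetic cardiomyocyte cross-section: tightly packed
#' myofibril polygons (seeded Voronoi cells separated by thin cytosolic gaps)
#' with mitochondria occupying whole inter-myofibril cells, extruded along the
#' cell axis to a half-sarcomere depth. Defaults follow ventricular myocyte
#' composition: half the cross-section myofibrils, a quarter mitochondria,
#' ~1.5 um myofibril calibre, 94.8 um^2 cross-section, 0.9 um depth.
#'
#' @param cross_section_area cross-section area (um^2).
#' @param myofibril_fraction,mitochondria_fraction target area fractions.
#' @param mito_clustering `"dispersed"` or `"clumped"`.
#' @param voxel_size voxel edge (um).
#' @param depth axial depth (um); the half-sarcomere.
#' @param sarcomere_length sarcomere length (um).
#' @param myofibril_scale typical myofibril calibre (um).
#' @export
template_spec <- function(cross_section_area = 94.8,
                          myofibril_fraction = 0.5,
                          mitochondria_fraction = 0.25,
                          mito_clustering = c("dispersed", "clumped"),
                          voxel_size = 0.05, depth = 0.9,
                          sarcomere_length = 1.8, myofibril_scale = 1.5) {
  mito_clustering <- match.arg(mito_clustering)
  if (cross_section_area <= 0) abort("area must be positive")
  if (myofibril_fraction < 0 || mitochondria_fraction < 0 ||
      myofibril_fraction + mitochondria_fraction >= 1)
    abort("fractions must be non-negative and sum to < 1")
  structure(list(cross_section_area = cross_section_area,
                 myofibril_fraction = myofibril_fraction,
                 mitochondria_fraction = mitochondria_fraction,
                 mito_clustering = mito_clustering,
                 voxel_size = voxel_size, depth = depth,
                 sarcomere_length = sarcomere_length,
                 myofibril_scale = myofibril_scale),
            class = "template_spec")
}

#' Generate a synthetic myofibril/mitochondria template
#'
#' Builds a 2D cross-section of Voronoi myofibril cells separated by thin
#' cytosolic gaps; a subset of cells is converted to mitochondria (randomly
#' spread or as one contiguous clump) until the target area fraction is
#' reached; the gap width is calibrated by bisection so the realised cytosol
#' fraction matches the spec. The section is then extruded to `depth`. The
#' z-disc plane is placed at the first axial slice and stored in the
#' `"zdisc_planes"` attribute.
#'
#' @param spec a [template_spec()].
#' @param seed RNG seed.
#' @return a `label_volume` with attribute `zdisc_planes`.
#' @export
make_template <- function(spec = template_spec(), seed = 1) {
  set.seed(seed)
  h <- spec$voxel_size
  side <- sqrt(spec$cross_section_area)
  nx <- max(8L, round(side / h))
  cyto_target <- 1 - spec$myofibril_fraction - spec$mitochondria_fraction

  # Voronoi seeds, lightly relaxed towards even packing by jittered lattice
  n_cells <- max(4L, round(spec$cross_section_area / spec$myofibril_scale^2))
  m <- ceiling(sqrt(n_cells))
  gx <- (rep(seq_len(m), m) - 0.5) * side / m
  gy <- (rep(seq_len(m), each = m) - 0.5) * side / m
  keep <- sample.int(m * m, n_cells)
  sx <- gx[keep] + rnorm(n_cells, 0, 0.15 * spec$myofibril_scale)
  sy <- gy[keep] + rnorm(n_cells, 0, 0.15 * spec$myofibril_scale)

  cc <- (seq_len(nx) - 0.5) * h
  px <- rep(cc, nx)
  py <- rep(cc, each = nx)
  # distance to nearest and second-nearest seed
  d1 <- rep(Inf, nx * nx); d2 <- rep(Inf, nx * nx)
  cell <- integer(nx * nx)
  for (s in seq_len(n_cells)) {
    ds <- sqrt((px - sx[s])^2 + (py - sy[s])^2)
    closer <- ds < d1
    d2 <- ifelse(closer, d1, pmin(d2, ds))
    cell[closer] <- s
    d1 <- pmin(d1, ds)
  }
  margin <- d2 - d1  # 0 on cell boundaries

  # calibrate the gap width so the cytosol fraction hits its target
  lo <- 0; hi <- 2 * spec$myofibril_scale
  for (it in 1:40) {
    g <- (lo + hi) / 2
    if (mean(margin < g) < cyto_target) lo <- g else hi <- g
  }
  gap <- (lo + hi) / 2
  lab2 <- ifelse(margin < gap, LBL_CYTO, LBL_MYO)

  # convert whole cells to mitochondria until the target fraction is reached
  if (spec$mitochondria_fraction > 0) {
    cell_area <- tabulate(cell[lab2 == LBL_MYO], nbins = n_cells) * h^2
    if (spec$mito_clustering == "dispersed") {
      ord <- sample.int(n_cells)
    } else {
      focal <- sample.int(n_cells, 1)
      ord <- order((sx - sx[focal])^2 + (sy - sy[focal])^2)
    }
    target_area <- spec$mitochondria_fraction * spec$cross_section_area
    acc <- 0
    mito_cells <- integer(0)
    for (s in ord) {
      if (acc >= target_area) break
      if (cell_area[s] == 0) next
      # stop before overshooting by more than half a cell
      if (acc + cell_area[s] > target_area + cell_area[s] / 2) next
      mito_cells <- c(mito_cells, s)
      acc <- acc + cell_area[s]
    }
    lab2[lab2 == LBL_MYO & cell %in% mito_cells] <- LBL_MITO
  }

  section <- array(as.integer(lab2), c(nx, nx, 1))
  nz <- max(1L, round(spec$depth / h))
  labs <- array(section, c(nx, nx, nz))
  vol <- label_volume(labs, h)
  attr(vol, "zdisc_planes") <- h / 2
  attr(vol, "spec") <- spec
  vol
}

#' z-disc planes of a template
#' @param volume a template produced by [make_template()] (or any
#'   `label_volume` with a `"zdisc_planes"` attribute).
#' @export
zdisc_planes <- function(volume) {
  p <- attr(volume, "zdisc_planes")
  if (is.null(p)) abort("volume carries no z-disc planes; use identify_zdiscs()")
  p
}

#' Generate a pattern with a prescribed nearest-neighbour distance law
#'
#' Ground-truth generator for recovery experiments: points are grown
#' sequentially, each placed at a distance drawn from
#' `Normal(nn_mean, nn_sd)` (truncated below at `min_spacing`) from a
#' randomly chosen existing point, in a uniformly random in-plane direction.
#' A candidate is accepted only if it falls in the admissible window and is
#' at least the drawn distance away from every other point, so the new
#' point's realised NN distance equals its draw.
#'
#' @param n number of points.
#' @param nn_mean,nn_sd NN-distance law (um).
#' @param window an `ryr_window` (mask type).
#' @param planes z-disc planes; points live on these planes.
#' @param seed RNG seed.
#' @param min_spacing hard-core distance (um).
#' @param max_tries placement attempts per point before giving up.
#' @details A candidate at drawn distance `d` from its anchor is accepted
#'   only if (i) the anchor's current NN distance is at most `d` (so the
#'   anchor's NN does not shrink) and (ii) every other point lies at least
#'   `max(d, its current NN distance)` away. Under this rule each accepted
#'   draw *is* the new point's realised NN distance and no existing NN
#'   distance ever changes, so the realised NN distribution equals the drawn
#'   truncated-normal sample.
#' @export
make_nn_pattern <- function(n, nn_mean = 0.59, nn_sd = 0.16, window, planes,
                            seed = 1, min_spacing = 0.2, max_tries = 5000) {
  if (window$type != "mask") abort("make_nn_pattern needs a mask window")
  set.seed(seed)
  d <- dim(window$mask)
  h <- window$voxel_size
  zc <- (seq_len(d[3]) - 0.5) * h[3]
  slices <- unique(vapply(planes, function(p) which.min(abs(zc - p)),
                          integer(1)))
  ok_xy <- which(apply(window$mask[, , slices, drop = FALSE], c(1, 2), any),
                 arr.ind = TRUE)
  if (nrow(ok_xy) < 1) abort("window admits no voxels on the z-disc planes")
  inside <- function(x, y) {
    i <- ceiling(x / h[1]); j <- ceiling(y / h[2])
    if (i < 1 || i > d[1] || j < 1 || j > d[2]) return(FALSE)
    any(window$mask[i, j, slices])
  }
  plane_z <- function(x, y) {
    i <- ceiling(x / h[1]); j <- ceiling(y / h[2])
    s <- slices[window$mask[i, j, slices]][1]
    planes[which.min(abs(planes - zc[s]))]
  }
  pts <- matrix(NA_real_, n, 3)
  nnd <- rep(Inf, n)  # current NN distance per placed point
  v0 <- ok_xy[sample.int(nrow(ok_xy), 1), ]
  x0 <- (v0[1] - 0.5 + runif(1) - 0.5) * h[1]
  y0 <- (v0[2] - 0.5 + runif(1) - 0.5) * h[2]
  if (!inside(x0, y0)) { x0 <- (v0[1] - 0.5) * h[1]; y0 <- (v0[2] - 0.5) * h[2] }
  pts[1, ] <- c(x0, y0, plane_z(x0, y0))
  # all NN distances are drawn up front and placed in ascending order, so an
  # anchor whose NN distance cannot shrink always exists
  draws <- numeric(0)
  while (length(draws) < n - 1) {
    d_new <- rnorm(n, nn_mean, nn_sd)
    draws <- c(draws, d_new[d_new > min_spacing])
  }
  draws <- sort(draws[seq_len(n - 1)])
  for (i in 2:n) {
    placed <- FALSE
    dd <- draws[i - 1]
    for (t in seq_len(2 * max_tries)) {
      strict <- t <= max_tries  # after max_tries, allow existing NNs to shrink
      # anchors whose NN distance cannot shrink by attaching at distance dd
      ok_anchor <- if (strict) which(nnd[seq_len(i - 1)] <= dd + 1e-12)
                   else seq_len(i - 1)
      if (length(ok_anchor) == 0) ok_anchor <- seq_len(i - 1)
      a <- ok_anchor[sample.int(length(ok_anchor), 1)]
      th <- runif(1, 0, 2 * pi)
      cx <- pts[a, 1] + dd * cos(th)
      cy <- pts[a, 2] + dd * sin(th)
      if (!inside(cx, cy)) next
      dall <- sqrt((pts[seq_len(i - 1), 1] - cx)^2 +
                   (pts[seq_len(i - 1), 2] - cy)^2)
      # keep every existing NN distance intact and make dd the new NN
      floor_d <- if (strict) pmax(dd, nnd[seq_len(i - 1)])
                 else rep(dd, i - 1)
      floor_d[a] <- dd
      if (any(dall < floor_d - 1e-12)) next
      pts[i, ] <- c(cx, cy, plane_z(cx, cy))
      nnd[i] <- dd
      nnd[seq_len(i - 1)] <- pmin(nnd[seq_len(i - 1)], dall)
      placed <- TRUE
      break
    }
    if (!placed)
      abort("could not place all points; window too crowded for this NN law")
  }
  ryr_pattern(pts)
}

#' Bundle a template, pattern and scan line for line-scan experiments
#'
#' Builds a small synthetic template, reconstructs a rat-preset cluster
#' pattern on it, and defines a transverse line through the template midline
#' at the z-disc plane. When the mitochondria fraction exceeds 0.2 the seed
#' is advanced (bounded, deterministic) until at least one mitochondrion
#' intersects the line.
#'
#' @param seed RNG seed.
#' @param spec a [template_spec()]; the default is a 16 um^2 test-sized
#'   section at 0.1 um voxels.
#' @param max_retry how many seeds to try for mitochondrion-line intersection.
#' @return a list: `volume`, `window`, `pattern`, `planes`, `line`
#'   (c(x0, y0, x1, y1) um at the z-disc plane).
#' @export
make_linescan_phantom <- function(seed = 1,
                                  spec = template_spec(
                                    cross_section_area = 16,
                                    voxel_size = 0.1),
                                  max_retry = 20) {
  for (k in seq_len(max_retry)) {
    vol <- make_template(spec, seed = seed + k - 1)
    ext <- volume_extent(vol)
    line <- c(0, ext[2] / 2, ext[1], ext[2] / 2)
    if (spec$mitochondria_fraction <= 0.2) break
    j <- max(1L, min(dim(vol$labels)[2],
                     as.integer(ceiling((ext[2] / 2) / vol$voxel_size[2]))))
    if (any(vol$labels[, j, 1] == LBL_MITO)) break
    if (k == max_retry)
      abort("no seed produced a mitochondrion on the scan line")
  }
  win <- build_window(vol)
  planes <- zdisc_planes(vol)
  preset <- species_presets("rat", cross_section_area = spec$cross_section_area)
  rec <- reconstruct(preset$targets, win, planes, seed = seed,
                     max_iter = 5e4)
  list(volume = vol, window = win, pattern = rec$pattern, planes = planes,
       line = line, preset = preset)
}
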