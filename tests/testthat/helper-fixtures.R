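# Shared fixtures, built once per test run. Everything is generated in code;
# geometries are kept small so individual files stay fast.

.fx <- new.env()

# small synthetic template (16 um^2, 0.1 um voxels) with window and planes
small_geom <- function() {
  if (is.null(.fx$small)) {
    vol <- make_template(template_spec(cross_section_area = 16,
                                       voxel_size = 0.1), seed = 11)
    .fx$small <- list(volume = vol, window = build_window(vol),
                      planes = zdisc_planes(vol))
  }
  .fx$small
}

# full-sized default template (94.8 um^2, 0.05 um voxels)
default_geom <- function() {
  if (is.null(.fx$full)) {
    vol <- make_template(template_spec(), seed = 1)
    .fx$full <- list(volume = vol, window = build_window(vol),
                     planes = zdisc_planes(vol))
  }
  .fx$full
}

# full-sized template at simulation resolution (0.1 um voxels) with a
# reconstructed rat pattern and release sites; shared by the end-to-end
# simulation checks
sim_geom <- function() {
  if (is.null(.fx$sim)) {
    vol <- make_template(template_spec(voxel_size = 0.1), seed = 1)
    win <- build_window(vol)
    planes <- zdisc_planes(vol)
    pre <- species_presets("rat", 94.8)
    rec <- reconstruct(pre$targets, win, planes, seed = 2)
    sites <- mark_release_sites(rec$pattern, vol)
    .fx$sim <- list(volume = vol, window = win, planes = planes,
                    preset = pre, recon = rec, sites = sites)
  }
  .fx$sim
}

# mid-sized template for transport-scale claims (49 um^2, 0.1 um voxels)
mid_geom <- function() {
  if (is.null(.fx$mid)) {
    vol <- make_template(template_spec(cross_section_area = 49,
                                       voxel_size = 0.1), seed = 11)
    win <- build_window(vol)
    planes <- zdisc_planes(vol)
    rec <- reconstruct(species_presets("rat", 49)$targets, win, planes,
                       seed = 4, max_iter = 1e5)
    .fx$mid <- list(volume = vol, window = win, planes = planes,
                    recon = rec,
                    sites = mark_release_sites(rec$pattern, vol))
  }
  .fx$mid
}

# brute-force nearest-neighbour distances (independent of the package path)
bf_nn <- function(m) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    min(sqrt(colSums((t(m[-i, , drop = FALSE]) - m[i, ])^2)))
  }, numeric(1))
}

# brute-force pairwise count within r of each point
bf_count_within <- function(m, r) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(m[-i, , drop = FALSE]) - m[i, ])^2))
    sum(d <= r)
  }, numeric(1))
}

# a strongly aggregated parent-offspring (Thomas-like) pattern in a box
clustered_pattern <- function(n_parents = 8, kids = 8, sigma = 0.15,
                              extent = c(8, 8, 1), seed = 5) {
  set.seed(seed)
  px <- runif(n_parents, 1, extent[1] - 1)
  py <- runif(n_parents, 1, extent[2] - 1)
  x <- rep(px, each = kids) + rnorm(n_parents * kids, 0, sigma)
  y <- rep(py, each = kids) + rnorm(n_parents * kids, 0, sigma)
  x <- pmin(pmax(x, 0), extent[1])
  y <- pmin(pmax(y, 0), extent[2])
  ryr_pattern(x, y, rep(extent[3] / 2, length(x)))
}

# an all-cytosol box volume for pure-diffusion experiments
box_volume <- function(nx, ny, nz, h = 0.1) {
  label_volume(array(0L, c(nx, ny, nz)), h)
}
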