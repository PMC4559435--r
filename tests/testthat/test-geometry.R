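test_that("z-disc planes are detected across 1-4 planes and noise", {
  set.seed(8)
  for (k in 1:4) {
    planes_true <- (seq_len(k) - 1) * 1.8
    n <- 60 * k
    ax <- sample(planes_true, n, replace = TRUE) + rnorm(n, 0, 0.05)
    pat <- ryr_pattern(runif(n, 0, 10), runif(n, 0, 10), ax)
    found <- identify_zdiscs(pat)
    expect_length(found, k)
    expect_lt(max(abs(sort(found) - planes_true)), 0.05)
  }
  # single-plane pattern: exactly one plane at that position
  pat1 <- ryr_pattern(runif(20), runif(20), rep(0.9, 20))
  expect_equal(identify_zdiscs(pat1), 0.9)
  expect_error(identify_zdiscs(ryr_pattern(numeric(0), numeric(0),
                                           numeric(0))), "empty")
})

test_that("snapping to z-discs follows the nearest-plane rule and is idempotent", {
  planes <- c(0, 1.8)
  p <- ryr_pattern(c(1, 2, 3), c(1, 2, 3), c(0.93, 0.1, 1.7))
  s <- snap_to_zdiscs(p, planes)
  expect_equal(s$z, c(1.8, 0, 1.8))   # |0.93-1.8| < |0.93-0|
  expect_equal(s$x, p$x)
  expect_equal(snap_to_zdiscs(s, planes)$z, s$z)  # idempotent
  # axial distances after snapping are all zero
  ax <- vapply(s$z, function(a) min(abs(planes - a)), numeric(1))
  expect_equal(ax, rep(0, 3))
})

test_that("admissible window matches the brute-force distance rule", {
  # small volume: myofibril block plus cytosol and a mitochondrion
  set.seed(3)
  labs <- array(0L, c(30, 30, 3))
  labs[12:18, 12:18, ] <- 1L
  labs[2:5, 2:5, ] <- 2L
  vol <- label_volume(labs, 0.05)
  win <- build_window(vol, max_radial = 0.7)

  myo <- which(labs == 1L, arr.ind = TRUE)
  ctr <- (myo - 0.5) * 0.05
  d <- dim(labs)
  for (probe in 1:200) {
    i <- sample(d[1], 1); j <- sample(d[2], 1); k <- sample(d[3], 1)
    p <- (c(i, j, k) - 0.5) * 0.05
    bf <- min(sqrt(colSums((t(ctr) - p)^2)))
    want <- labs[i, j, k] == 0L && bf <= 0.7 + 1e-9
    expect_identical(unname(win$mask[i, j, k]), want)
    expect_lt(abs(win$dist_myo[i, j, k] - bf), 1e-9)
  }
  # myofibril and mitochondria voxels excluded
  expect_false(any(win$mask[labs == 1L]))
  expect_false(any(win$mask[labs == 2L]))
  expect_error(build_window(label_volume(array(1L, c(3, 3, 3)), 0.1)),
               "all myofibril")
})

test_that("0.7 um window includes 0.69 and excludes 0.71 um voxels", {
  labs <- array(0L, c(40, 3, 3))
  labs[1, , ] <- 1L  # myofibril plane at x index 1
  vol <- label_volume(labs, 0.05)
  win <- build_window(vol, max_radial = 0.7)
  # voxel centers at (i - 0.5)*0.05; distance to myofibril center = (i-1)*0.05
  expect_true(win$mask[15, 2, 2])   # distance 0.70
  expect_true(win$mask[14, 2, 2])   # distance 0.65
  expect_false(win$mask[16, 2, 2])  # distance 0.75
})

test_that("distance profile is conservative and consistent", {
  geom <- small_geom()
  pat <- simulate_csr(geom$window, 40, seed = 4)
  pat <- snap_to_zdiscs(pat, geom$planes)
  prof <- distance_profile(pat, geom$volume, geom$planes)
  expect_equal(sum(prof$radial_hist$count), 40)
  expect_equal(sum(prof$axial_hist$count), 40)
  expect_true(all(prof$distances$radial >= 0))
  expect_equal(prof$distances$axial, rep(0, 40))
  expect_true(all(prof$distances$radial <= 0.7 + sqrt(3) * 0.1))
})

test_that("half-sarcomere extrusion tiles reflectively and preserves fractions", {
  set.seed(12)
  labs <- array(sample(0:2, 20 * 20 * 5, replace = TRUE), c(20, 20, 5))
  sec <- label_volume(labs, c(0.05, 0.05, 0.05))
  out <- extrude_half_sarcomere(sec, target_depth = 0.9)
  expect_equal(dim(out$labels)[3], 18)
  # each output slice is a copy of an input slice: per-slice fractions exact
  order <- rep_len(c(1:5, 5:1), 18)
  for (k in 1:18)
    expect_identical(out$labels[, , k], labs[, , order[k]])
  # mirror symmetry at the first reflection boundary (slices 5|6)
  for (d in 1:3)
    expect_identical(out$labels[, , 5 + d], out$labels[, , 6 - d])
  # identity when already at target depth
  same <- extrude_half_sarcomere(out, target_depth = 0.9)
  expect_identical(same$labels, out$labels)
  expect_error(extrude_half_sarcomere(out, target_depth = 0.5), "smaller")
})

test_that("release sites realise the nominal sphere volume and eligibility", {
  expect_equal(sim_params()$v_release, 4 / 3 * pi * 0.1^3)
  # refinement: voxel-sum volume converges to the sphere volume (mean over
  # random placements)
  nominal <- 4 / 3 * pi * 0.1^3
  set.seed(31)
  err_of <- function(h) {
    n <- round(1 / h)
    vol <- box_volume(n, n, n, h)
    mean(vapply(1:10, function(i) {
      ctr <- runif(3, 0.4, 0.6)
      s <- mark_release_sites(ryr_pattern(ctr[1], ctr[2], ctr[3]), vol)
      abs(s[[1]]$volume_um3 - nominal) / nominal
    }, numeric(1)))
  }
  e05 <- err_of(0.05)
  e02 <- err_of(0.02)
  expect_lt(e02, 0.05)
  expect_lt(e02, e05)
  # centroid inside a mitochondrion: empty site plus warning
  labs <- array(0L, c(10, 10, 10))
  labs[4:7, 4:7, 4:7] <- 2L
  vol <- label_volume(labs, 0.1)
  expect_warning(
    sites <- mark_release_sites(ryr_pattern(0.55, 0.55, 0.55), vol),
    "no eligible")
  expect_false(sites[[1]]$active)
  expect_equal(sites[[1]]$volume_um3, 0)
})

test_that("label volumes round-trip through multi-page TIFF", {
  geom <- small_geom()
  f <- tempfile(fileext = ".tif")
  write_label_volume(geom$volume, f)
  back <- read_label_volume(f)
  expect_identical(back$labels, geom$volume$labels)
  expect_equal(back$voxel_size, geom$volume$voxel_size)
})
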