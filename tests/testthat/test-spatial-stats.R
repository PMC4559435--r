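test_that("G equals definition and brute-force CDF", {
  # two points at distance 0.5: step from 0 to 1 at 0.5
  p <- ryr_pattern(c(0, 0.5), c(0, 0), c(0, 0))
  g <- estimate_G(p, c(0.2, 0.49, 0.5, 1))
  expect_equal(g$value, c(0, 0, 1, 1))

  # seeded uniform points: exact match with the all-pairs oracle
  set.seed(42)
  m <- cbind(runif(20), runif(20), runif(20))
  pat <- ryr_pattern(m)
  r_grid <- seq(0.01, 1, by = 0.01)
  g <- estimate_G(pat, r_grid)
  nnd <- bf_nn(m)
  expect_equal(g$value,
               vapply(r_grid, function(r) mean(nnd <= r), numeric(1)))
  expect_true(all(diff(g$value) >= 0))
  expect_true(all(g$value >= 0 & g$value <= 1))
  expect_error(estimate_G(ryr_pattern(0, 0, 0), c(0.1)), "2 points")
})

test_that("F matches the Poisson closed form and basic properties", {
  win <- box_window(c(20, 20, 20))
  pat <- simulate_csr(win, n_points = round(0.1 * 20^3), seed = 3)
  r_grid <- seq(0, 2, by = 0.1)
  f <- estimate_F(pat, win, r_grid, n_test_points = 4000, seed = 9)
  expect_equal(f$value[1], 0)          # F(0) = 0
  expect_true(all(diff(f$value) >= 0))
  # the border-corrected estimate is unbiased for the Poisson closed form
  fb <- estimate_F(pat, win, r_grid, n_test_points = 4000, seed = 9,
                   correction = "border")
  lambda <- 0.1
  closed <- 1 - exp(-lambda * 4 / 3 * pi * r_grid^3)
  expect_lt(max(abs(fb$value - closed)), 0.03)
  # the uncorrected estimate is biased low near the boundary, never high
  expect_lt(max(f$value - closed), 0.03)
  expect_error(estimate_F(pat, win, r_grid, n_test_points = 10), ">= 100")
})

test_that("K equals the pairwise-counting oracle exactly", {
  # two points at distance d: K jumps from 0 to 1/lambda at d
  win <- box_window(c(4, 4, 4))
  p2 <- ryr_pattern(c(1, 2.25), c(1, 1), c(1, 1))
  k2 <- estimate_K(p2, win, c(0.5, 1.24, 1.25, 2))
  lam <- 2 / 64
  expect_equal(k2$value, c(0, 0, 1 / lam, 1 / lam))

  set.seed(7)
  m <- cbind(runif(15, 0, 4), runif(15, 0, 4), runif(15, 0, 4))
  pat <- ryr_pattern(m)
  r_grid <- seq(0.1, 2, by = 0.1)
  k <- estimate_K(pat, win, r_grid)
  lam <- 15 / 64
  oracle <- vapply(r_grid, function(r) mean(bf_count_within(m, r)) / lam,
                   numeric(1))
  expect_equal(k$value, oracle)
  expect_true(all(diff(k$value) >= 0))
})

test_that("CSR K stays inside the 99-simulation envelope of (4/3) pi r^3", {
  win <- box_window(c(10, 10, 10))
  n <- 200
  obs <- simulate_csr(win, n, seed = 21)
  r_grid <- seq(0.1, 1, by = 0.05)  # up to one-tenth of the box edge
  env <- envelope_test(obs, function(s) simulate_csr(win, n, seed = s),
                       n_sims = 99, statistics = "K", r_grid = r_grid,
                       window = win, seed = 31)
  csr_k <- 4 / 3 * pi * r_grid^3
  e <- env$K
  expect_true(all(csr_k >= e$lower - 1e-9 & csr_k <= e$upper + 1e-9))
  expect_identical(envelope_verdicts(env)[["K"]], "inside")
})

test_that("PCF recovers the CSR identity and hard-core zeros", {
  r <- seq(0.05, 2, by = 0.05)
  ok <- 4:(length(r) - 3)   # ends use one-sided stencils and partial smoothing
  k2d <- ryrscape:::new_curve(r, pi * r^2, "K")
  g2 <- estimate_pcf(k2d, dimension = 2)
  expect_lt(max(abs(g2$value[ok] - 1)), 1e-6)   # exact: quadratic K
  k3d <- ryrscape:::new_curve(r, 4 / 3 * pi * r^3, "K")
  g3 <- estimate_pcf(k3d, dimension = 3)
  # cubic K picks up the O(dr^2 / r^2) differentiation bias; bounded away
  # from the origin it sits below 2%
  mid <- which(r >= 0.6 & r <= 1.9)
  expect_lt(max(abs(g3$value[mid] - 1)), 0.02)

  # hard-core pattern: grid spacing 0.5, PCF ~ 0 below the spacing
  g <- expand.grid(x = seq(0.5, 7.5, by = 0.5), y = seq(0.5, 7.5, by = 0.5))
  pat <- ryr_pattern(g$x, g$y, rep(0.5, nrow(g)))
  win <- box_window(c(8, 8, 1))
  k <- estimate_K(pat, win, seq(0.05, 1, by = 0.05))
  pcf <- estimate_pcf(k, dimension = 2)
  expect_true(all(pcf$value[pcf$r < 0.3] == 0, na.rm = TRUE))
  expect_error(estimate_pcf(g3, dimension = 2), "K curve")
})

test_that("PCF of CSR fluctuates around 1", {
  win <- box_window(c(10, 10, 10))
  obs <- simulate_csr(win, 300, seed = 5)
  k <- estimate_K(obs, win, seq(0.1, 1.2, by = 0.1))
  pcf <- estimate_pcf(k, dimension = 3)
  expect_gt(mean(pcf$value, na.rm = TRUE), 0.8)
  expect_lt(mean(pcf$value, na.rm = TRUE), 1.2)
})

test_that("simulate_csr respects the admissible mask and occupancy", {
  geom <- small_geom()
  p0 <- simulate_csr(geom$window, 0, seed = 1)
  expect_equal(nrow(p0), 0)
  pat <- simulate_csr(geom$window, 150, seed = 2)
  m <- as.matrix(pat[, c("x", "y", "z")])
  expect_true(all(ryrscape:::window_contains(geom$window, m)))

  # two-region occupancy proportional to admissible volume (binomial check)
  ext <- dim(geom$window$mask)[1] * geom$window$voxel_size[1]
  half <- ext / 2
  vol_left <- sum(geom$window$mask[seq_len(dim(geom$window$mask)[1] %/% 2), , ])
  frac_left <- vol_left / length(geom$window$idx)
  set.seed(99)
  counts <- vapply(1:200, function(s) {
    p <- simulate_csr(geom$window, 20, seed = 1000 + s)
    sum(p$x <= half)
  }, numeric(1))
  bt <- binom.test(sum(counts), 200 * 20, p = frac_left)
  expect_gt(bt$p.value, 1e-4)
})

test_that("envelope test judges its own null inside and flags aggregation", {
  win <- box_window(c(8, 8, 1))
  r_grid <- seq(0.05, 1.5, by = 0.05)
  # observed drawn from the null stays inside in >= 90 of 100 seeded trials
  rg <- seq(0.1, 1.2, by = 0.1)
  n_inside <- 0
  for (t in 1:100) {
    obs <- simulate_csr(win, 60, seed = 5000 + t)
    env <- envelope_test(obs, function(s) simulate_csr(win, 60, seed = s),
                         n_sims = 99, statistics = "G", r_grid = rg,
                         window = win, seed = t)
    if (envelope_verdicts(env)[["G"]] == "inside") n_inside <- n_inside + 1
  }
  expect_gte(n_inside, 90)

  # a strongly aggregated pattern exits the CSR envelopes for G, K and PCF
  obs <- clustered_pattern()
  env <- envelope_test(obs, function(s) simulate_csr(win, nrow(obs), seed = s),
                       n_sims = 99, statistics = c("G", "K", "PCF"),
                       r_grid = r_grid, window = win, seed = 17)
  v <- envelope_verdicts(env)
  expect_identical(unname(v[c("G", "K", "PCF")]),
                   rep("outside", 3))
})

test_that("curves and envelopes round-trip through CSV", {
  p <- ryr_pattern(runif(10), runif(10), runif(10))
  g <- estimate_G(p, seq(0.1, 1, by = 0.1))
  f <- tempfile(fileext = ".csv")
  write_curve(g, f)
  back <- read.csv(f)
  expect_equal(back$r_um, g$r)
  expect_equal(back$value, g$value)
})
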