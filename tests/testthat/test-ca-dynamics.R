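test_that("equilibrium initialisation reproduces resting buffer occupancies", {
  vol <- box_volume(4, 4, 4)
  st <- equilibrium_init(sim_params(), default_buffers(), vol)
  expect_equal(st$bound$fluo4[1], 25 * 0.1 / (0.1 + 1.1))     # 2.083 uM
  expect_equal(st$bound$troponin[1],
               70 * 0.1 / (0.1 + 0.0196 / 0.0327))  # 10.009 uM
  expect_equal(st$ca[1], 0.1)
  # zero resting Ca: buffers fully unbound
  st0 <- equilibrium_init(sim_params(ca_rest = 0), default_buffers(), vol)
  expect_equal(max(abs(st0$bound$fluo4)), 0)
  expect_equal(max(abs(st0$bound$troponin)), 0)
})

test_that("latency sampling is exponential, reproducible and non-negative", {
  l <- sample_latencies(10000, tau = 6.7, seed = 2)
  expect_lt(abs(mean(l) - 6.7) / 6.7, 0.02)
  expect_true(all(l >= 0))
  expect_identical(sample_latencies(50, seed = 3), sample_latencies(50, seed = 3))
  expect_error(sample_latencies(10, tau = -1), "positive")
})

test_that("release flux converts current to concentration rate correctly", {
  params <- sim_params()
  site <- list(cluster_id = 1, center = c(0, 0, 0), voxels = 1:4,
               volume_um3 = 4 / 3 * pi * 0.1^3, latency = 2, active = TRUE)
  prof <- release_profile(i_peak = 2, rise = 1, decay = 2.6)
  # peak current 2 pA in the nominal sphere volume: i/(zF V)
  flux_peak <- release_flux(site, t = 3, params, prof)  # 1 ms past latency
  expect_equal(flux_peak, 2 * 1e6 / (2 * 96500 * 4 / 3 * pi * 0.1^3))
  expect_equal(flux_peak, 2.47e3, tolerance = 0.005)
  expect_equal(release_flux(site, t = 1.9, params, prof), 0)  # before latency
  site$active <- FALSE
  expect_equal(release_flux(site, t = 3, params, prof), 0)
})

test_that("reaction step is a fixed point at equilibrium and matches the
           closed-form relaxation", {
  vol <- box_volume(3, 3, 3)
  bufs <- default_buffers()
  st <- equilibrium_init(sim_params(), bufs, vol)
  st2 <- reaction_step(st, bufs, dt = 0.5)
  expect_lt(max(abs(st2$ca - st$ca)), 1e-12)
  expect_lt(max(abs(st2$bound$fluo4 - st$bound$fluo4)), 1e-12)

  # single Fluo-4 voxel with Ca clamped at 1 uM: linearised relaxation
  # towards 25*1/2.1 at rate k_on*Ca + k_off = 0.21 /ms
  f4 <- bufs$fluo4
  b <- 0           # start fully unbound
  ca_clamp <- 1
  dt <- 0.001
  for (s in 1:2000) {  # 2 ms
    b <- b + dt * (f4$k_on * ca_clamp * (f4$total - b) - f4$k_off * b)
  }
  beq <- 25 * 1 / 2.1
  closed <- beq * (1 - exp(-(f4$k_on * ca_clamp + f4$k_off) * 2))
  expect_equal(b, closed, tolerance = 1e-3)

  # the package's exact pair update conserves Ca + bound exactly
  upd <- ryrscape:::react_pair(c(5, 0.3), c(1, 2), f4$total, f4$k_on,
                               f4$k_off, 0.7)
  expect_equal(upd$ca + upd$bound, c(6, 2.3))
  expect_true(all(upd$ca >= 0 & upd$bound >= 0))
  # long horizon reaches the analytic equilibrium root
  upd2 <- ryrscape:::react_pair(5, 1, f4$total, f4$k_on, f4$k_off, 1e4)
  S <- 6; KD <- 1.1
  root <- (-(f4$total - S + KD) + sqrt((f4$total - S + KD)^2 + 4 * KD * S)) / 2
  expect_equal(upd2$ca, root, tolerance = 1e-10)
})

test_that("diffusion matches the free-space Gaussian and conserves mass", {
  vol <- box_volume(41, 41, 41, 0.1)
  params <- sim_params()
  bufs <- default_buffers()
  st <- equilibrium_init(sim_params(ca_rest = 1e-12), bufs, vol)
  st$ca <- rep(0, st$domain$n)
  ctr_idx <- which(st$domain$idx ==
                     (21 + 20 * 41 + 20 * 41 * 41))
  st$ca[ctr_idx] <- 1000
  total0 <- sum(st$ca)
  dt <- 0.001
  for (s in 1:1000) st <- diffusion_step(st, params, bufs, dt)  # t = 1 ms
  expect_equal(sum(st$ca), total0, tolerance = 1e-9)  # zero-flux conservation

  # analytic free-space kernel, amount A = 1000 * h^3
  h <- 0.1
  A <- 1000 * h^3
  D <- params$d_ca
  co <- (c(21, 21, 21) - 0.5) * h
  ai <- arrayInd(st$domain$idx, st$domain$dims)
  r2 <- colSums((t((ai - 0.5) * h) - co)^2)
  analytic <- A / (4 * pi * D * 1)^1.5 * exp(-r2 / (4 * D * 1))
  rms <- sqrt(mean((st$ca - analytic)^2)) / max(analytic)
  expect_lt(rms, 0.02)

  # uniform field is unchanged
  stu <- equilibrium_init(sim_params(), bufs, vol)
  stu2 <- diffusion_step(stu, params, bufs, 0.001)
  expect_equal(stu2$ca, stu$ca)
  expect_error(diffusion_step(stu, params, bufs, dt = 1), "stability")
})

test_that("two-state gating stays in [0,1] and decays exponentially when closed", {
  rates <- list(alpha = 0.2, eta = 2, k_close = 0.5)
  set.seed(14)
  for (i in 1:50) {
    p <- runif(1)
    ca <- runif(1, 0, 50)
    dt <- runif(1, 1e-3, 1)
    p2 <- two_state_gating_step(p, ca, dt, rates)
    expect_true(p2 >= 0 && p2 <= 1)
  }
  # alpha = 0 after trigger: pure exponential decay at k_close
  p <- 0.02
  p2 <- two_state_gating_step(p, ca = 1, dt = 2,
                              rates = list(alpha = 0, eta = 2, k_close = 0.5))
  expect_equal(p2, 0.02 * exp(-0.5 * 2))
  expect_equal(sim_params()$trigger_po, 1 / 50)
  expect_error(two_state_gating_step(0.1, 1, 0.1, list(alpha = 1)),
               "gating rates")
})

test_that("no-release simulation is stationary and a release run conserves mass", {
  geom <- small_geom()
  sites0 <- structure(list(), class = "ryr_sites")
  sim0 <- simulate_transient(geom$volume, sites0, sim_params(t_end = 30))
  expect_lt(max(abs(sim0$state$ca - 0.1)), 1e-9)
  expect_lt(max(abs(sim0$trace$f_f0 - 1)), 1e-9)

  pre <- species_presets("rat", 16)
  rec <- reconstruct(pre$targets, geom$window, geom$planes, seed = 4,
                     max_iter = 3e4)
  sites <- mark_release_sites(rec$pattern, geom$volume)
  sim <- simulate_transient(geom$volume, sites, sim_params(t_end = 30),
                            record_slice = 1)
  expect_lt(max(abs(sim$trace$mass_rel_err)), 1e-3)   # 0.1 % budget
  expect_true(all(sim$state$ca >= 0))
  expect_gt(sim$trace$f_f0[nrow(sim$trace)], 1)
  # deactivating every site reproduces the stationary solution
  off <- deactivate_clusters(sites, c(0, 0, 0), length(sites))
  sim_off <- simulate_transient(geom$volume, off, sim_params(t_end = 5))
  expect_lt(max(abs(sim_off$state$ca - 0.1)), 1e-9)
  # k = 0 is the identity
  same <- deactivate_clusters(sites, c(0, 0, 0), 0)
  expect_identical(vapply(same, function(s) s$active, logical(1)),
                   vapply(sites, function(s) s$active, logical(1)))
})

test_that("grid refinement changes the averaged transient only mildly", {
  # one physical phantom, exactly representable at both voxel sizes:
  # 2.4 x 2.4 x 0.4 um box with a myofibril slab and a mitochondrion block
  phantom <- function(h) {
    n <- round(2.4 / h)
    nz <- round(0.4 / h)
    labs <- array(0L, c(n, n, nz))
    xs <- (seq_len(n) - 0.5) * h
    labs[xs > 0.8 & xs < 1.2, , ] <- 1L
    labs[xs > 1.6 & xs < 2.0, xs > 0.8 & xs < 1.2, ] <- 2L
    label_volume(labs, h)
  }
  pat <- ryr_pattern(c(0.6, 1.45, 2.2), c(1.2, 0.6, 2.2), c(0.2, 0.2, 0.2))
  lat <- c(1, 4, 8)
  sims <- lapply(c(0.1, 0.05), function(h) {
    vol <- phantom(h)
    sites <- mark_release_sites(pat, vol)
    simulate_transient(vol, sites,
                       sim_params(t_end = 15, dt = if (h == 0.1) 0.005
                                  else 0.00125),
                       latencies = lat)
  })
  rel <- abs(sims[[2]]$trace$f_f0 - sims[[1]]$trace$f_f0) /
    sims[[1]]$trace$f_f0
  expect_lt(max(rel), 0.03)
})
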