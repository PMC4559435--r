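#' Calcium buffer specification
#'
#' One Ca-binding species with mass-action kinetics
#' `Ca + B <-> CaB` (`k_on`, `k_off`, dissociation constant
#' `K_D = k_off / k_on`). Mobile buffers (dye) diffuse as a free/bound pair
#' with a common diffusivity, so the total stays spatially uniform; stationary
#' buffers (Troponin C) have zero diffusivity.
#'
#' @param name buffer name.
#' @param total total concentration (uM).
#' @param k_on association rate (1 / (uM ms)).
#' @param k_off dissociation rate (1 / ms).
#' @param diffusivity bound/free diffusivity (um^2 / ms); 0 = stationary.
#' @export
buffer_spec <- function(name, total, k_on, k_off, diffusivity = 0) {
  if (total <= 0 || k_on <= 0 || k_off <= 0)
    abort("total and rate constants must be positive")
  if (diffusivity < 0) abort("diffusivity must be >= 0")
  structure(list(name = name, total = total, k_on = k_on, k_off = k_off,
                 diffusivity = diffusivity, K_D = k_off / k_on),
            class = "buffer_spec")
}

#' Default buffer set: Fluo-4 dye and Troponin C
#'
#' Fluo-4: 25 uM total, k_on 0.1 /(uM ms), k_off 0.11 /ms (K_D 1.1 uM),
#' diffusing at 0.042 um^2/ms (free dye is assigned the bound-dye diffusivity:
#' same molecule give or take one ion). Troponin C: 70 uM total, k_on
#' 0.0327 /(uM ms), k_off 0.0196 /ms (K_D 0.6 uM), stationary, carried
#' uniformly over the diffusive domain.
#' @export
default_buffers <- function() {
  list(fluo4 = buffer_spec("fluo4", total = 25, k_on = 0.1, k_off = 0.11,
                           diffusivity = 0.042),
       troponin = buffer_spec("troponin", total = 70, k_on = 0.0327,
                              k_off = 0.0196, diffusivity = 0))
}

#' Simulation parameters
#'
#' Physical and numerical parameters of the reaction-diffusion model of the
#' rising Ca transient. Defaults: cytosolic Ca diffusivity 0.22 um^2/ms,
#' resting Ca 0.1 uM, 2 pA release current per cluster, 100 nm release-sphere
#' radius (nominal volume 4/3 pi r^3 = 4.19e-3 um^3), exponential trigger
#' latency with mean 6.7 ms, 30 ms duration. The release profile is a
#' triangular pulse: linear rise over `release_rise` ms to `i_ca`, linear
#' decay over `release_decay` ms; the decay length was calibrated once so the
#' reference rat scenario reaches an average free Ca of about 1 uM at 30 ms,
#' and is frozen here.
#'
#' @param d_ca free Ca diffusivity (um^2/ms).
#' @param ca_rest resting free Ca (uM).
#' @param i_ca per-cluster release current (pA).
#' @param faraday Faraday constant (C/mol).
#' @param valence ionic valence of Ca.
#' @param release_radius release-sphere radius (um).
#' @param latency_tau mean trigger latency (ms).
#' @param t_end simulated duration (ms).
#' @param dt time step (ms); must satisfy the explicit stability bound
#'   `dt <= h_min^2 / (6 D_max)`.
#' @param release_rise,release_decay triangular release-profile times (ms).
#' @param n_ryr RyR channels per cluster (gating model).
#' @param trigger_po open probability imposed at the trigger (gating model);
#'   the default `1 / n_ryr` is one open channel out of the cluster.
#' @param seed RNG seed for trigger latencies.
#' @export
sim_params <- function(d_ca = 0.22, ca_rest = 0.1, i_ca = 2,
                       faraday = 96500, valence = 2, release_radius = 0.1,
                       latency_tau = 6.7, t_end = 30, dt = 0.005,
                       release_rise = 1, release_decay = 2.6,
                       n_ryr = 50, trigger_po = 1 / n_ryr, seed = 1) {
  p <- list(d_ca = d_ca, ca_rest = ca_rest, i_ca = i_ca, faraday = faraday,
            valence = valence, release_radius = release_radius,
            v_release = 4 / 3 * pi * release_radius^3,
            latency_tau = latency_tau, t_end = t_end, dt = dt,
            release_rise = release_rise, release_decay = release_decay,
            n_ryr = n_ryr, trigger_po = trigger_po, seed = seed)
  if (any(unlist(p[c("d_ca", "i_ca", "faraday", "valence", "release_radius",
                     "latency_tau", "t_end", "dt")]) <= 0))
    abort("physical parameters must be positive")
  structure(p, class = "sim_params")
}

# diffusive domain of a volume: everything that is not mitochondria, with a
# 6-neighbour adjacency table (0 = closed face: outer boundary or mitochondria)
build_domain <- function(volume) {
  d <- dim(volume$labels)
  idx <- which(volume$labels != LBL_MITO)
  n <- length(idx)
  pos <- array(0L, d)
  pos[idx] <- seq_len(n)
  ai <- arrayInd(idx, d)
  offs <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
                c(0L, 0L, -1L), c(0L, 0L, 1L))
  nbr <- matrix(0L, n, 6)
  for (k in 1:6) {
    co <- ai + matrix(offs[k, ], n, 3, byrow = TRUE)
    inb <- co[, 1] >= 1 & co[, 1] <= d[1] & co[, 2] >= 1 & co[, 2] <= d[2] &
      co[, 3] >= 1 & co[, 3] <= d[3]
    lin <- co[inb, 1] + (co[inb, 2] - 1L) * d[1] +
      (co[inb, 3] - 1L) * d[1] * d[2]
    nbr[inb, k] <- pos[lin]
  }
  list(idx = idx, nbr = nbr, n = n, dims = d,
       voxel_size = volume$voxel_size,
       voxel_volume = prod(volume$voxel_size))
}

#' Initialise simulation state at chemical equilibrium
#'
#' Every domain voxel starts at the resting Ca concentration with each buffer
#' at binding equilibrium: `bound = total * Ca / (Ca + K_D)`. With Table-type
#' defaults this gives 2.08 uM bound Fluo-4 (22.92 uM free) and 10 uM
#' Ca-bound Troponin C (60 uM free).
#'
#' @param params a [sim_params()].
#' @param buffers list of [buffer_spec()].
#' @param volume a `label_volume` (or a prebuilt domain).
#' @return an `ryr_state`: free Ca and per-buffer bound fields on the domain
#'   voxels, the time, and the cumulative injected amount.
#' @export
equilibrium_init <- function(params, buffers, volume) {
  domain <- if (is.list(volume) && !is.null(volume$nbr)) volume
            else build_domain(volume)
  ca <- rep(params$ca_rest, domain$n)
  bound <- lapply(buffers, function(b)
    rep(b$total * params$ca_rest / (params$ca_rest + b$K_D), domain$n))
  names(bound) <- vapply(buffers, function(b) b$name, character(1))
  structure(list(ca = ca, bound = bound, time = 0, injected = 0,
                 domain = domain),
            class = "ryr_state")
}

#' Sample stochastic trigger latencies
#'
#' Independent exponential latencies (mean `tau`) for each release site,
#' mimicking the stochastic coupling delay between L-type channels and RyR
#' clusters.
#'
#' @param n_sites number of sites (or an `ryr_sites` object).
#' @param tau mean latency (ms).
#' @param seed RNG seed.
#' @export
sample_latencies <- function(n_sites, tau = 6.7, seed = NULL) {
  if (inherits(n_sites, "ryr_sites")) n_sites <- length(n_sites)
  if (tau <= 0) abort("tau must be positive")
  if (!is.null(seed)) set.seed(seed)
  rexp(n_sites, rate = 1 / tau)
}

#' Triangular release-current profile
#'
#' Piecewise-linear current (pA): rise from 0 to `i_peak` over `rise` ms,
#' then decay back to 0 over `decay` ms.
#'
#' @param i_peak peak current (pA).
#' @param rise,decay rise and decay times (ms).
#' @return a tibble of `(t, i)` nodes of class `release_profile`; evaluate
#'   with [release_current()].
#' @export
release_profile <- function(i_peak = 2, rise = 1, decay = 2.6) {
  out <- tibble(t = c(0, rise, rise + decay), i = c(0, i_peak, 0))
  class(out) <- c("release_profile", class(out))
  out
}

#' @rdname release_profile
#' @param profile a `release_profile`.
#' @param t times since the site's trigger (ms).
#' @export
release_current <- function(profile, t) {
  i <- approx(profile$t, profile$i, xout = t, yleft = 0, yright = 0,
              rule = 2)$y
  i[t < 0 | t > max(profile$t)] <- 0
  i
}

#' Release flux into a site's voxels
#'
#' Converts the site current at time `t` into a concentration rate (uM/ms)
#' spread uniformly over the site's realised voxel volume:
#' `flux = i(t - latency) * 1e6 / (valence * F * V_site)`, so that
#' `flux * V_site` integrated over time equals the injected amount. Zero
#' before the latency or for inactive sites.
#'
#' @param site one element of an `ryr_sites` object.
#' @param t absolute time (ms).
#' @param params a [sim_params()].
#' @param profile a `release_profile`; defaults to the params' triangle.
#' @export
release_flux <- function(site, t, params, profile = NULL) {
  if (!site$active || site$volume_um3 <= 0) return(0)
  if (is.null(profile))
    profile <- release_profile(params$i_ca, params$release_rise,
                               params$release_decay)
  i <- release_current(profile, t - site$latency)
  i * 1e6 / (params$valence * params$faraday * site$volume_um3)
}

# exact update of one Ca/buffer pair over dt (Riccati closed form); the pair
# invariant ca + bound is conserved to machine precision
react_pair <- function(ca, bound, total, k_on, k_off, dt) {
  react_pair_cpp(ca, bound, total, k_on, k_off, dt)
}

#' Advance buffer kinetics over one step
#'
#' Updates `d[bound]/dt = k_on Ca (total - bound) - k_off bound` and the
#' matching Ca sink for each buffer in turn, using the exact closed-form
#' solution of the two-species mass-action system, which conserves
#' `Ca + bound` per pair to machine precision and preserves positivity for
#' any `dt`.
#'
#' @param state an `ryr_state`.
#' @param buffers list of [buffer_spec()].
#' @param dt time step (ms).
#' @export
reaction_step <- function(state, buffers, dt) {
  if (dt <= 0) abort("dt must be positive")
  for (b in buffers) {
    upd <- react_pair(state$ca, state$bound[[b$name]], b$total, b$k_on,
                      b$k_off, dt)
    state$ca <- upd$ca
    state$bound[[b$name]] <- upd$bound
  }
  if (any(state$ca < 0)) abort("negative concentration after reaction step")
  state
}

#' Advance diffusion over one step
#'
#' Explicit finite-volume diffusion of free Ca and of each mobile buffer's
#' bound field over the voxel domain. All faces to mitochondria, the outer
#' boundary and both axial ends are zero-flux, so total content is conserved
#' by construction. Refuses time steps violating the stability bound
#' `dt <= h_min^2 / (6 D_max)`.
#'
#' @param state an `ryr_state`.
#' @param params a [sim_params()].
#' @param buffers list of [buffer_spec()].
#' @param dt time step (ms).
#' @export
diffusion_step <- function(state, params, buffers, dt) {
  domain <- state$domain
  h <- domain$voxel_size
  d_max <- max(params$d_ca, vapply(buffers, function(b) b$diffusivity,
                                   numeric(1)))
  bound_dt <- min(h)^2 / (6 * d_max)
  if (dt > bound_dt + 1e-12)
    abort(sprintf("dt = %g violates the stability bound %.3g ms", dt,
                  bound_dt))
  coef_of <- function(D) dt * D / c(h[1], h[1], h[2], h[2], h[3], h[3])^2
  state$ca <- as.numeric(diffuse_step_cpp(state$ca, domain$nbr,
                                          coef_of(params$d_ca)))
  for (b in buffers) {
    if (b$diffusivity > 0)
      state$bound[[b$name]] <- as.numeric(
        diffuse_step_cpp(state$bound[[b$name]], domain$nbr,
                         coef_of(b$diffusivity)))
  }
  state
}

#' Deterministic two-state RyR gating update
#'
#' Mean-field open probability of a cluster of RyRs:
#' `dp/dt = k_open(Ca) (1 - p) - k_close p` with `k_open(Ca) = alpha Ca^eta`,
#' advanced exactly over `dt` (the rate is frozen at the step's Ca). The
#' trigger raises `p` to 0.02 — one open channel out of 50 — at the site's
#' latency.
#'
#' @param p current open probability.
#' @param ca local Ca (uM).
#' @param dt time step (ms).
#' @param rates list with `alpha`, `eta`, `k_close`.
#' @return updated `p`, guaranteed in [0, 1].
#' @export
two_state_gating_step <- function(p, ca, dt, rates) {
  if (is.null(rates$alpha) || is.null(rates$eta) || is.null(rates$k_close))
    abort("gating rates must provide alpha, eta and k_close")
  a <- rates$alpha * ca^rates$eta
  tot <- a + rates$k_close
  pinf <- ifelse(tot > 0, a / tot, p)
  pinf + (p - pinf) * exp(-tot * dt)
}

#' Silence the k release sites nearest to a location
#'
#' Marks the `k` sites nearest `center` as inactive (un-activated clusters)
#' and reports the spatial span of the silenced group (maximum pairwise
#' centroid distance, um) in the `"span_diameter"` attribute.
#'
#' @param sites an `ryr_sites` object.
#' @param center reference location `(x, y, z)` (um).
#' @param k number of sites to silence (0 = identity).
#' @export
deactivate_clusters <- function(sites, center, k) {
  if (k > length(sites)) abort("k exceeds the number of sites")
  if (k > 0) {
    ctr <- t(vapply(sites, function(s) s$center, numeric(3)))
    dd <- sqrt(colSums((t(ctr) - center)^2))
    pick <- order(dd)[seq_len(k)]
    for (i in pick) sites[[i]]$active <- FALSE
    span <- if (k == 1) 0 else max(dist(ctr[pick, , drop = FALSE]))
  } else span <- 0
  attr(sites, "span_diameter") <- span
  sites
}

#' Simulate the rising Ca transient
#'
#' Integrates the coupled reaction-diffusion system on the voxel domain with
#' Strang operator splitting (half reaction + release, full diffusion, half
#' reaction + release) for `t_end` ms. Mitochondria are diffusion barriers
#' excluded from the domain; the outer boundary and both axial ends are
#' zero-flux. Trigger latencies are exponential unless supplied. A mass audit
#' (free + bound content versus initial content + cumulative injection) is
#' carried along the recorded trace.
#'
#' @param volume a `label_volume`.
#' @param sites an `ryr_sites` object from [mark_release_sites()].
#' @param params a [sim_params()].
#' @param buffers list of [buffer_spec()].
#' @param gating `"none"` (prescribed release profile) or `"two_state"`
#'   (mean-field RyR gating; needs `gating_params`).
#' @param gating_params list with `alpha`, `eta`, `k_close`, `i_single` (pA).
#' @param record recording cadence (ms) for the summary trace.
#' @param record_slice axial slice index whose Fluo-4-bound-Ca field is
#'   snapshotted at each record time (for line scans); `NULL` to skip.
#' @param latencies optional per-site trigger latencies (ms); sampled from
#'   `Exp(latency_tau)` with `params$seed` when `NULL`.
#' @param profile optional `release_profile` shared by all sites.
#' @return an `ryr_sim`: `trace` tibble (time, ca_mean, f4ca_mean, f_f0,
#'   mass_rel_err), final fields, optional plane snapshots, and inputs.
#' @export
simulate_transient <- function(volume, sites, params = sim_params(),
                               buffers = default_buffers(),
                               gating = c("none", "two_state"),
                               gating_params = NULL,
                               record = 1, record_slice = NULL,
                               latencies = NULL, profile = NULL) {
  gating <- match.arg(gating)
  if (gating == "two_state" && is.null(gating_params))
    abort("two_state gating needs gating_params (alpha, eta, k_close, i_single)")
  domain <- build_domain(volume)
  state <- equilibrium_init(params, buffers, domain)
  dyename <- names(state$bound)[1]
  f4ca0 <- state$bound[[dyename]][1]

  if (is.null(latencies))
    latencies <- sample_latencies(length(sites), params$latency_tau,
                                  seed = params$seed)
  for (i in seq_along(sites)) sites[[i]]$latency <- latencies[i]
  if (is.null(profile))
    profile <- release_profile(params$i_ca, params$release_rise,
                               params$release_decay)

  act <- which(vapply(sites, function(s) s$active && s$volume_um3 > 0,
                      logical(1)))
  site_pos <- lapply(sites[act], function(s) match(s$voxels, domain$idx))
  site_vol <- vapply(sites[act], function(s) s$volume_um3, numeric(1))
  site_lat <- vapply(sites[act], function(s) s$latency, numeric(1))
  site_cur <- vapply(sites[act], function(s)
    if (!is.null(s$current_pA)) s$current_pA else params$i_ca, numeric(1))
  conv <- 1e6 / (params$valence * params$faraday)  # pA -> uM um^3 / ms
  p_open <- rep(0, length(act))

  dt <- params$dt
  n_steps <- round(params$t_end / dt)
  vv <- domain$voxel_volume
  amount0 <- (sum(state$ca) +
                sum(vapply(state$bound, sum, numeric(1)))) * vv

  inject <- function(state, t_mid, dtv) {
    tloc <- t_mid - site_lat
    i_pa <- if (gating == "two_state") {
      ifelse(tloc < 0, 0, params$n_ryr * p_open * gating_params$i_single)
    } else {
      release_current(profile, tloc) * site_cur / params$i_ca
    }
    for (si in which(i_pa > 0)) {
      rate <- i_pa[si] * conv / site_vol[si]  # uM/ms in each site voxel
      state$ca[site_pos[[si]]] <- state$ca[site_pos[[si]]] + rate * dtv
      state$injected <- state$injected + i_pa[si] * conv * dtv
    }
    state
  }

  rec_times <- seq(record, params$t_end, by = record)
  trace <- vector("list", length(rec_times))
  snaps <- if (!is.null(record_slice)) vector("list", length(rec_times))
           else NULL
  rec_i <- 1

  for (s in seq_len(n_steps)) {
    t0 <- (s - 1) * dt
    if (gating == "two_state") {
      for (si in seq_along(act)) {
        if (t0 >= site_lat[si]) {
          if (p_open[si] == 0) p_open[si] <- params$trigger_po
          ca_site <- mean(state$ca[site_pos[[si]]])
          p_open[si] <- two_state_gating_step(p_open[si], ca_site, dt,
                                              gating_params)
        }
      }
    }
    state <- inject(state, t0 + dt / 4, dt / 2)
    state <- reaction_step(state, buffers, dt / 2)
    state <- diffusion_step(state, params, buffers, dt)
    state <- inject(state, t0 + 3 * dt / 4, dt / 2)
    state <- reaction_step(state, buffers, dt / 2)
    state$time <- s * dt

    while (rec_i <= length(rec_times) &&
           state$time >= rec_times[rec_i] - dt / 2) {
      amt <- (sum(state$ca) +
                sum(vapply(state$bound, sum, numeric(1)))) * vv
      rel_err <- (amt - amount0 - state$injected) /
        max(amount0 + state$injected, .Machine$double.eps)
      trace[[rec_i]] <- tibble(
        time = rec_times[rec_i],
        ca_mean = mean(state$ca),
        f4ca_mean = mean(state$bound[[dyename]]),
        f_f0 = mean(state$bound[[dyename]]) / f4ca0,
        mass_rel_err = rel_err)
      if (!is.null(record_slice))
        snaps[[rec_i]] <- field_slice(state, domain, dyename, record_slice)
      rec_i <- rec_i + 1
    }
  }

  structure(list(trace = bind_rows(trace), state = state, domain = domain,
                 volume = volume, sites = sites, params = params,
                 buffers = buffers, f4ca0 = f4ca0,
                 snapshots = snaps, record_slice = record_slice,
                 record_times = rec_times, latencies = latencies),
            class = "ryr_sim")
}

# extract one axial slice of a domain field as a 2D matrix (mitochondria NA)
field_slice <- function(state, domain, fieldname, slice) {
  arr <- array(NA_real_, domain$dims)
  f <- if (fieldname == "ca") state$ca else state$bound[[fieldname]]
  arr[domain$idx] <- f
  arr[, , slice]
}

#' Extract a simulated field as a 3D array
#'
#' @param sim an `ryr_sim`.
#' @param field `"ca"` or a buffer name (bound concentration).
#' @param fill value given to mitochondria voxels (default `NA`).
#' @export
sim_field <- function(sim, field = "ca", fill = NA_real_) {
  arr <- array(fill, sim$domain$dims)
  f <- if (field == "ca") sim$state$ca else sim$state$bound[[field]]
  arr[sim$domain$idx] <- f
  arr
}

#' @export
print.ryr_sim <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "<ryr_sim: %d voxels, %d sites, t = %g ms | <Ca> = %.3g uM, F/F0 = %.3g>\n",
    x$domain$n, length(x$sites), last$time, last$ca_mean, last$f_f0))
  invisible(x)
}
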